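#' Recovery curve container
#'
#' Ordered (x, richness) points tracing OTU recovery along a swept parameter:
#' a simulated sequencing depth (reads) or a two-fraction mixing ratio (%).
#'
#' @param x numeric vector, strictly increasing.
#' @param richness non-negative integer richness at each `x`.
#' @param strategy label of the strategy or sweep the curve belongs to.
#' @param xlab axis label for the swept parameter.
#' @param provenance free-form list (thresholds, preparation mode, inputs).
#' @return object of class `recovery_curve` (a data frame with attributes).
#' @export
recovery_curve <- function(x, richness, strategy = "", xlab = "x",
                           provenance = list()) {
  if (any(diff(x) <= 0)) stop("x must be strictly increasing")
  if (any(richness < 0) || any(richness != floor(richness))) {
    stop("richness must be non-negative integers")
  }
  structure(data.frame(x = x, richness = as.integer(richness)),
            strategy = strategy, xlab = xlab, provenance = provenance,
            class = c("recovery_curve", "data.frame"))
}

#' @export
print.recovery_curve <- function(x, ...) {
  cat(sprintf("recovery_curve '%s' (%d points, %s)\n",
              attr(x, "strategy"), nrow(x), attr(x, "xlab")))
  print.data.frame(x, ...)
  invisible(x)
}

#' @export
plot.recovery_curve <- function(x, ..., log = "") {
  plot(x$x, x$richness, type = "b", pch = 16, log = log,
       xlab = attr(x, "xlab"), ylab = "OTU richness",
       main = attr(x, "strategy"), ...)
  invisible(x)
}

#' Filtering threshold equivalent to a sequencing depth
#'
#' Threshold-based rarefaction replaces read resampling with a deterministic
#' abundance cut: simulating a depth of `d` reads means requiring at least
#' one expected read, i.e. a relative abundance of `100/d` percent. For
#' example, depth 500 gives 0.2% and depth 50,000 gives 0.002%.
#'
#' @param depth simulated sequencing depth in reads (>= 1).
#' @return threshold in percent.
#' @export
#' @examples
#' threshold_for_depth(500)    # 0.2
#' threshold_for_depth(50000)  # 0.002
threshold_for_depth <- function(depth) {
  if (any(depth < 1)) stop("depth must be >= 1")
  100 / depth
}

#' Threshold-based rarefaction of one sample
#'
#' Returns the OTUs surviving a simulated sequencing depth: those whose
#' relative abundance reaches [threshold_for_depth()] of the depth. An OTU
#' exactly at the threshold is retained; only OTUs that do not reach it are
#' excluded. Deterministic — no resampling, hence no rarefaction noise.
#'
#' @param x a named count vector, single-sample [otu_table] or
#'   [pooled_profile].
#' @param depth simulated depth in reads.
#' @return character vector of surviving OTU ids.
#' @export
rarefy_by_threshold <- function(x, depth) {
  thr <- threshold_for_depth(depth) / 100
  r <- as_rel_abundance(x)
  names(r)[r >= thr & r > 0]
}

#' Log-spaced depth grid
#'
#' @param from,to depth range in reads (defaults 500 to 50,000).
#' @param n number of grid points (default 19).
#' @return integer vector of depths, endpoints included.
#' @export
depth_grid <- function(from = 500, to = 50000, n = 19) {
  round(exp(seq(log(from), log(to), length.out = n)))
}

#' Recovery curves over simulated sequencing depths
#'
#' Computes, for each strategy sample, OTU richness at every depth of the
#' grid via [rarefy_by_threshold()]. Curves are non-decreasing in depth by
#' construction (larger depth, lower threshold, nested survivors).
#'
#' Callers choose the upstream preparation and should record it in `mode`:
#' `"fig3"` = replicates summed directly, without replicate-consistency or
#' 0.01% filtering; `"filtered"` = post [quality_filter()] tables.
#'
#' @param tables named list (names = strategy/sample labels) of inputs
#'   coercible to relative abundances.
#' @param depths numeric vector of depths (default [depth_grid()]).
#' @param mode preparation-mode label recorded in each curve's provenance.
#' @return named list of [recovery_curve] objects.
#' @export
recovery_curves <- function(tables, depths = depth_grid(), mode = "fig3") {
  depths <- sort(unique(depths))
  lapply(stats::setNames(names(tables), names(tables)), function(lab) {
    r <- as_rel_abundance(tables[[lab]])
    rich <- vapply(depths, function(d) length(rarefy_by_threshold(r, d)), 0L)
    recovery_curve(depths, rich, strategy = lab, xlab = "depth (reads)",
                   provenance = list(mode = mode))
  })
}

#' Depth-equivalence factors between pooling strategies
#'
#' For a reference strategy at a reference depth, finds for every other
#' strategy the smallest grid depth at which it matches (or exceeds) the
#' reference's richness. The factor `reference_depth / depth_needed` is the
#' sequencing-depth saving of that strategy over the reference; lookup is on
#' the grid, not interpolated, to avoid implying false precision.
#'
#' @param curves named list of [recovery_curve]s sharing one depth grid that
#'   contains `reference_depth`.
#' @param reference label of the reference strategy (default `"g"`, the
#'   unsorted-sample reconstruction).
#' @param reference_depth reference depth in reads (default 50,000).
#' @return data frame with columns `strategy`, `target_richness`,
#'   `depth_needed` (NA when never reached), `factor` (NA when never
#'   reached), `reached`.
#' @export
depth_equivalence_factor <- function(curves, reference = "g",
                                     reference_depth = 50000) {
  if (!reference %in% names(curves)) {
    stop("reference strategy '", reference, "' not among the curves")
  }
  ref <- curves[[reference]]
  i <- match(reference_depth, ref$x)
  if (is.na(i)) stop("reference_depth is not on the curves' depth grid")
  target <- ref$richness[i]
  out <- lapply(names(curves), function(lab) {
    if (lab == reference) {
      return(data.frame(strategy = lab, target_richness = target,
                        depth_needed = reference_depth, factor = 1,
                        reached = TRUE, stringsAsFactors = FALSE))
    }
    cv <- curves[[lab]]
    j <- which(cv$richness >= target)
    if (length(j)) {
      d <- cv$x[min(j)]
      data.frame(strategy = lab, target_richness = target, depth_needed = d,
                 factor = reference_depth / d, reached = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(strategy = lab, target_richness = target,
                 depth_needed = NA_real_, factor = NA_real_, reached = FALSE,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, out)
  out[order(match(out$strategy, names(curves))), , drop = FALSE]
}
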