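#' Define a lysate-pooling scheme
#'
#' A pooling scheme gives the volume share each size fraction contributes to
#' a pooled lysate. Because the lysis buffer volume is scaled to tissue
#' weight, DNA concentration is assumed uniform across lysates, so volume
#' shares weight the fractions' read compositions directly.
#'
#' @param name scheme label, e.g. `"g"`, `"equ"`, `"log"` or a custom name.
#' @param proportions named numeric vector of shares over fractions (names
#'   from S, M, L, XL); must be non-negative and sum to 1 within 1e-9.
#' @return an object of class `pooling_scheme`.
#' @export
#' @examples
#' pooling_scheme("equ", c(S = 0.25, M = 0.25, L = 0.25, XL = 0.25))
pooling_scheme <- function(name, proportions) {
  if (is.null(names(proportions)) ||
      !all(names(proportions) %in% FRACTIONS)) {
    stop("proportions must be named with fractions from {S, M, L, XL}")
  }
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-9) {
    stop("proportions must be non-negative and sum to 1")
  }
  structure(list(name = name, proportions = proportions),
            class = "pooling_scheme")
}

#' @export
print.pooling_scheme <- function(x, ...) {
  cat(sprintf("pooling_scheme '%s': %s\n", x$name,
              paste(sprintf("%s=%.4f", names(x$proportions), x$proportions),
                    collapse = ", ")))
  invisible(x)
}

#' Built-in pooling strategies
#'
#' Returns the six named strategies as `pooling_scheme` objects, ordered from
#' large-dominated to small-enriched:
#' \describe{
#'   \item{g}{dry-weight proportional — simulates an unsorted bulk sample;
#'     requires `weights`.}
#'   \item{equ}{equal quarters.}
#'   \item{invg}{normalised reciprocals of the dry-weight shares — inverts
#'     the biomass dominance; requires `weights`.}
#'   \item{fibo}{Fibonacci shares (5,3,2,1)/11 over (S,M,L,XL).}
#'   \item{4x}{each smaller fraction 4x the next larger: (64,16,4,1)/85.}
#'   \item{log}{decade steps: (1000,100,10,1)/1111.}
#' }
#' All proportions except `g` and `equ` are conventional defaults and freely
#' overridable via [pooling_scheme()].
#'
#' @param weights named numeric vector of per-fraction dry weights for the
#'   source sample (required for `g` and `invg`). Zero weights are allowed
#'   for `g`; `invg` requires all weights positive.
#' @return named list of [pooling_scheme] objects.
#' @export
default_schemes <- function(weights = NULL) {
  schemes <- list(
    equ = pooling_scheme("equ", stats::setNames(rep(0.25, 4), FRACTIONS)),
    fibo = pooling_scheme("fibo",
      stats::setNames(c(5, 3, 2, 1) / 11, FRACTIONS)),
    `4x` = pooling_scheme("4x",
      stats::setNames(c(64, 16, 4, 1) / 85, FRACTIONS)),
    log = pooling_scheme("log",
      stats::setNames(c(1000, 100, 10, 1) / 1111, FRACTIONS))
  )
  if (!is.null(weights)) {
    w <- weights[FRACTIONS]
    names(w) <- FRACTIONS
    if (anyNA(w)) stop("weights must cover all four fractions")
    if (sum(w) <= 0) stop("all fraction weights are zero")
    schemes$g <- pooling_scheme("g", w / sum(w))
    if (all(w > 0)) {
      schemes$invg <- pooling_scheme("invg", (1 / w) / sum(1 / w))
    }
  }
  schemes[intersect(STRATEGIES, names(schemes))]
}

#' Construct a pooled relative-abundance profile
#'
#' @param rel named numeric vector of relative abundances; non-negative and,
#'   when any OTU is present, summing to 1 within 1e-9.
#' @param provenance free-form list recording constituents, scheme, depth.
#' @return an object of class `pooled_profile`.
#' @export
pooled_profile <- function(rel, provenance = list()) {
  if (length(rel) && is.null(names(rel))) stop("profile must be named by OTU id")
  if (any(rel < 0)) stop("relative abundances must be non-negative")
  s <- sum(rel)
  if (length(rel) && s > 0 && abs(s - 1) > 1e-9) {
    stop("relative abundances must sum to 1")
  }
  structure(list(rel = rel, provenance = provenance), class = "pooled_profile")
}

#' @export
print.pooled_profile <- function(x, ...) {
  cat(sprintf("pooled_profile: %d OTUs", length(x$rel)))
  if (!is.null(x$provenance$scheme)) cat(sprintf(", scheme '%s'", x$provenance$scheme))
  cat("\n")
  invisible(x)
}

# Coerce a count vector / one-column otu_table / profile to a named
# relative-abundance vector.
as_rel_abundance <- function(x) {
  if (inherits(x, "pooled_profile")) return(x$rel)
  if (inherits(x, "otu_table")) {
    if (ncol(x$counts) != 1) stop("expected a single-sample otu_table")
    v <- x$counts[, 1]
  } else {
    v <- x
  }
  if (is.null(names(v))) stop("counts must be named by OTU id")
  rel_abundance(v)
}

#' Pool size-fraction profiles under a scheme
#'
#' Mixes the relative-abundance compositions of the given fractions with the
#' scheme's volume shares: `profile_i = sum_f scheme_f * relabund[f, i]` over
#' the union of OTU ids (an OTU absent from a fraction contributes zero).
#'
#' @param fraction_tables named list (names = fractions) of per-fraction
#'   inputs: a named count vector, a single-sample [otu_table], or a
#'   [pooled_profile].
#' @param scheme a [pooling_scheme]; every fraction with nonzero share must be
#'   present in `fraction_tables`.
#' @return a [pooled_profile] with provenance recording the scheme and
#'   constituent fractions.
#' @export
pool_by_scheme <- function(fraction_tables, scheme) {
  stopifnot(inherits(scheme, "pooling_scheme"))
  used <- names(scheme$proportions)[scheme$proportions > 0]
  missing <- setdiff(used, names(fraction_tables))
  if (length(missing)) {
    stop("scheme '", scheme$name, "' needs absent fraction(s): ",
         paste(missing, collapse = ", "))
  }
  # OTU universe: union over every supplied fraction, including zero-share
  # ones, so absent OTUs appear explicitly at zero
  rels <- lapply(fraction_tables, as_rel_abundance)
  universe <- unique(unlist(lapply(rels, names)))
  mix <- stats::setNames(numeric(length(universe)), universe)
  total_share <- 0
  for (f in used) {
    r <- rels[[f]]
    if (sum(r) == 0) next  # empty fraction contributes nothing
    mix[names(r)] <- mix[names(r)] + scheme$proportions[[f]] * r
    total_share <- total_share + scheme$proportions[[f]]
  }
  if (total_share > 0) mix <- mix / total_share
  pooled_profile(mix, provenance = list(scheme = scheme$name,
                                        proportions = scheme$proportions,
                                        fractions = used))
}

#' Pool size fractions proportionally to dry weight
#'
#' Weight-proportional pooling reconstructs the composition an unsorted bulk
#' sample would have produced, because each fraction's lysate volume tracks
#' its tissue weight. Equivalent to [pool_by_scheme()] with shares
#' `weight_f / sum(weights)`.
#'
#' @param fraction_tables as in [pool_by_scheme()].
#' @param weights named numeric vector of dry weights (same names as
#'   `fraction_tables`), or a data frame with columns `source`, `fraction`,
#'   `weight` together with `source`.
#' @param source source-sample label selecting rows when `weights` is a data
#'   frame.
#' @return a [pooled_profile].
#' @export
pool_by_weight <- function(fraction_tables, weights, source = NULL) {
  if (is.data.frame(weights)) {
    if (is.null(source)) stop("source is required with a weights data frame")
    w <- weights[weights$source == source, , drop = FALSE]
    weights <- stats::setNames(w$weight, w$fraction)
  }
  weights <- weights[names(fraction_tables)]
  names(weights) <- names(fraction_tables)
  if (anyNA(weights)) stop("weights missing for some fractions")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (sum(weights) == 0) stop("all fraction weights are zero")
  scheme <- pooling_scheme("by_weight", weights / sum(weights))
  out <- pool_by_scheme(fraction_tables, scheme)
  out$provenance$weights <- weights
  if (!is.null(source)) out$provenance$source <- source
  out
}

#' Combine two quality-filtered fractions by dry weight
#'
#' Convenience wrapper building the reconstructed "small" (S+M) or "large"
#' (L+XL) composite used by [two_fraction_sweep()]: a weight-proportional
#' two-way pool of already-filtered fraction libraries.
#'
#' @param table_f1,table_f2 single-fraction inputs (named count vector,
#'   single-sample [otu_table] or [pooled_profile]).
#' @param weights numeric vector of length two: dry weights of fraction 1 and
#'   fraction 2.
#' @param fractions labels for the two fractions (defaults `"f1"`, `"f2"`).
#' @return a [pooled_profile].
#' @export
build_combined_fraction <- function(table_f1, table_f2, weights,
                                    fractions = c("S", "M")) {
  stopifnot(length(weights) == 2, length(fractions) == 2)
  tabs <- list(table_f1, table_f2)
  names(tabs) <- fractions
  pool_by_weight(tabs, stats::setNames(weights, fractions))
}

#' Two-fraction in silico mixing-ratio sweep
#'
#' Mixes a "small" composite (S+M) and a "large" composite (L+XL) at ratios
#' running from 100% small / 0% large down to 0% small / 100% large in
#' `step_pct` steps. At each ratio the mixed relative abundances are
#' thresholded — OTUs strictly below `threshold_pct` percent are dropped,
#' matching expected read counts at the stated depth — and the surviving OTU
#' richness is recorded. Thresholding operates on fractional expected counts;
#' no rounding to integers.
#'
#' @param small,large [pooled_profile]s (or inputs coercible via the pooling
#'   functions) for the small and large composites.
#' @param step_pct ratio step in percent; must divide 100 (default 5).
#' @param depth nominal sequencing depth in reads (default 10000); recorded
#'   in provenance and used to express expected counts.
#' @param threshold_pct relative-abundance cut in percent (default 0.01).
#' @return a [recovery_curve] with `x` = percent of the small composite in
#'   the mix (0 to 100) and `richness` = surviving OTU count.
#' @export
two_fraction_sweep <- function(small, large, step_pct = 5, depth = 10000,
                               threshold_pct = 0.01) {
  if (100 %% step_pct != 0) stop("step_pct must divide 100")
  rs <- as_rel_abundance(small)
  rl <- as_rel_abundance(large)
  universe <- unique(c(names(rs), names(rl)))
  vs <- stats::setNames(numeric(length(universe)), universe)
  vl <- vs
  vs[names(rs)] <- rs
  vl[names(rl)] <- rl
  ratios <- seq(0, 100, by = step_pct)
  richness <- integer(length(ratios))
  for (i in seq_along(ratios)) {
    r <- ratios[i]
    mix <- (r / 100) * vs + (1 - r / 100) * vl
    richness[i] <- sum(mix >= threshold_pct / 100 & mix > 0)
  }
  recovery_curve(x = ratios, richness = richness,
                 strategy = "two_fraction_sweep", xlab = "% small (S+M)",
                 provenance = list(step_pct = step_pct, depth = depth,
                                   threshold_pct = threshold_pct))
}

#' Equal quarter-depth pool of the four fractions
#'
#' Simulates pooling the four individually sequenced size fractions at one
#' quarter of the sequencing depth each: every fraction is filtered at
#' `per_fraction_threshold_pct` of its own total (0.04% at quarter depth is
#' the 0.01% full-depth cut), and the richness of the union of survivors is
#' returned.
#'
#' @param fraction_tables named list of the four per-fraction inputs for one
#'   source sample (names S, M, L, XL).
#' @param per_fraction_threshold_pct per-fraction relative-abundance cut in
#'   percent (default 0.04).
#' @return integer richness; attribute `"otus"` holds the surviving OTU ids.
#' @export
equal_quarter_pool <- function(fraction_tables,
                               per_fraction_threshold_pct = 0.04) {
  missing <- setdiff(FRACTIONS, names(fraction_tables))
  if (length(missing)) {
    stop("missing fraction(s): ", paste(missing, collapse = ", "))
  }
  surviving <- character()
  for (f in FRACTIONS) {
    r <- as_rel_abundance(fraction_tables[[f]])
    surviving <- union(surviving,
                       names(r)[r >= per_fraction_threshold_pct / 100 & r > 0])
  }
  structure(length(surviving), otus = surviving)
}
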