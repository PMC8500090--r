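#' Pair extraction replicates
#'
#' Builds the replicate pairing used by [replicate_consistency_filter()].
#' Non-control libraries are grouped by (source, category, fraction, strategy);
#' groups of exactly two samples become a pair. Groups of one are left
#' unpaired (the filter warns and passes them through); groups of more than
#' two are an error because the pairing would be ambiguous.
#'
#' @param x an [otu_table] or a sample-metadata data frame.
#' @return data frame with columns `rep1`, `rep2` (sample ids) and the shared
#'   metadata columns `source`, `category`, `fraction`, `strategy`.
#' @export
replicate_pairing <- function(x) {
  s <- if (inherits(x, "otu_table")) x$samples else as.data.frame(x)
  s <- s[s$category != "negative_control", , drop = FALSE]
  key <- paste(s$source, s$category, s$fraction, s$strategy, sep = "\r")
  pairs <- lapply(split(s, key), function(g) {
    if (nrow(g) > 2) {
      stop("more than two replicates for ", g$source[1], " / ",
           ifelse(g$category[1] == "fraction", g$fraction[1], g$strategy[1]))
    }
    if (nrow(g) < 2) return(NULL)
    g <- g[order(g$replicate), , drop = FALSE]
    data.frame(rep1 = g$sample_id[1], rep2 = g$sample_id[2],
               source = g$source[1], category = g$category[1],
               fraction = g$fraction[1], strategy = g$strategy[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pairs)
  if (is.null(out)) {
    out <- data.frame(rep1 = character(), rep2 = character(),
                      source = character(), category = character(),
                      fraction = character(), strategy = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Subtract negative-control signal
#'
#' For each OTU, takes the maximum read count observed across all
#' negative-control libraries and subtracts it from that OTU's count in every
#' other library, flooring at zero. The negative-control columns are then
#' dropped. This removes contamination carried through extraction and PCR at
#' the level of the worst control.
#'
#' @param x an [otu_table] containing at least one negative-control sample.
#' @return an [otu_table] without negative-control columns.
#' @export
subtract_negative_controls <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  isnc <- x$samples$category == "negative_control"
  if (!any(isnc)) {
    stop("no negative-control samples present; skip this step explicitly if intended")
  }
  nc_ids <- x$samples$sample_id[isnc]
  m <- apply(x$counts[, nc_ids, drop = FALSE], 1, max)
  keep_ids <- x$samples$sample_id[!isnc]
  counts <- pmax(x$counts[, keep_ids, drop = FALSE] - m, 0)
  samples <- x$samples[!isnc, , drop = FALSE]
  rownames(samples) <- NULL
  otu_table(counts, samples = samples, taxonomy = x$taxonomy)
}

#' Per-sample relative-abundance filter
#'
#' Zeroes, within each sample column, every count whose share of that column's
#' total is strictly below `threshold_pct` percent. Counts sitting exactly at
#' the threshold are kept. Column totals are computed once, before any
#' zeroing, so the filter is a single pass (re-running it with totals
#' recomputed could cascade).
#'
#' @param x an [otu_table].
#' @param threshold_pct minimum relative abundance in percent (default 0.01,
#'   i.e. 1 read in 10,000).
#' @return an [otu_table] with sub-threshold counts set to zero.
#' @export
relative_abundance_filter <- function(x, threshold_pct = 0.01) {
  stopifnot(inherits(x, "otu_table"), threshold_pct >= 0)
  counts <- x$counts
  totals <- colSums(counts)
  for (j in seq_len(ncol(counts))) {
    if (totals[j] == 0) next
    drop <- counts[, j] / totals[j] < threshold_pct / 100
    counts[drop, j] <- 0
  }
  otu_table(counts, samples = x$samples, taxonomy = x$taxonomy)
}

#' Replicate-consistency filter and replicate merging
#'
#' For each extraction-replicate pair and OTU, a count present in only one of
#' the two replicates is treated as unreliable: if either replicate is zero,
#' both are zeroed. The surviving counts of the pair are then summed into one
#' merged column that inherits the shared metadata (replicate index dropped).
#' Unpaired non-control samples are passed through unchanged with a warning.
#'
#' @param x an [otu_table].
#' @param pairing replicate pairing as returned by [replicate_pairing()];
#'   defaults to pairing inferred from the sample metadata.
#' @return an [otu_table] with one merged column per pair.
#' @export
replicate_consistency_filter <- function(x, pairing = replicate_pairing(x)) {
  stopifnot(inherits(x, "otu_table"))
  ids <- c(pairing$rep1, pairing$rep2)
  if (anyDuplicated(ids)) stop("a sample id appears in more than one pair")
  missing <- setdiff(ids, colnames(x$counts))
  if (length(missing)) stop("pairing refers to absent samples: ",
                            paste(missing, collapse = ", "))
  unpaired <- setdiff(x$samples$sample_id[x$samples$category != "negative_control"],
                      ids)
  if (length(unpaired)) {
    warning("unpaired samples passed through unmerged: ",
            paste(unpaired, collapse = ", "))
  }
  merged_counts <- list()
  merged_meta <- list()
  for (i in seq_len(nrow(pairing))) {
    a <- x$counts[, pairing$rep1[i]]
    b <- x$counts[, pairing$rep2[i]]
    both <- a > 0 & b > 0
    merged_counts[[i]] <- ifelse(both, a + b, 0)
    lab <- ifelse(pairing$category[i] == "fraction",
                  pairing$fraction[i], pairing$strategy[i])
    merged_meta[[i]] <- data.frame(
      sample_id = paste(pairing$source[i], lab, sep = "_"),
      source = pairing$source[i], category = pairing$category[i],
      fraction = pairing$fraction[i], strategy = pairing$strategy[i],
      replicate = NA_integer_, stringsAsFactors = FALSE)
  }
  keep <- setdiff(colnames(x$counts), ids)
  counts <- cbind(x$counts[, keep, drop = FALSE],
                  do.call(cbind, merged_counts))
  samples <- rbind(x$samples[match(keep, x$samples$sample_id), , drop = FALSE],
                   do.call(rbind, merged_meta))
  if (length(merged_counts)) {
    colnames(counts) <- c(keep, vapply(merged_meta, function(m) m$sample_id, ""))
  }
  rownames(samples) <- NULL
  otu_table(counts, samples = samples, taxonomy = x$taxonomy)
}

#' Full OTU-table quality filter
#'
#' Composes the three cleanup steps in their standard order: (1) subtract the
#' per-OTU maximum negative-control count from all samples, (2) zero counts
#' below `threshold_pct` percent relative abundance per sample, (3) zero
#' counts not present in both extraction replicates and merge each replicate
#' pair by summation. OTUs left with all-zero counts are dropped at the end,
#' so the per-step log stays interpretable.
#'
#' @param x an [otu_table].
#' @param pairing replicate pairing; defaults to [replicate_pairing()] on `x`.
#' @param threshold_pct relative-abundance threshold in percent (default 0.01).
#' @param skip_negatives skip the negative-control subtraction (e.g. when the
#'   table carries no controls).
#' @param order character vector giving the step order; reordering is offered
#'   for sensitivity analysis only.
#' @return an [otu_table]; attribute `"filter_log"` holds a data frame with
#'   reads and OTUs removed per step.
#' @export
quality_filter <- function(x, pairing = NULL, threshold_pct = 0.01,
                           skip_negatives = FALSE,
                           order = c("negatives", "threshold", "replicates")) {
  stopifnot(inherits(x, "otu_table"))
  order <- match.arg(order, c("negatives", "threshold", "replicates"),
                     several.ok = TRUE)
  if (skip_negatives) order <- setdiff(order, "negatives")
  log <- data.frame(step = character(), reads_removed = numeric(),
                    otus_removed = integer(), stringsAsFactors = FALSE)
  richness <- function(t) sum(rowSums(t$counts) > 0)
  for (step in order) {
    before_reads <- sum(x$counts)
    before_rich <- richness(x)
    x <- switch(step,
      negatives = subtract_negative_controls(x),
      threshold = relative_abundance_filter(x, threshold_pct),
      replicates = {
        p <- if (is.null(pairing)) replicate_pairing(x) else pairing
        replicate_consistency_filter(x, p)
      })
    log <- rbind(log, data.frame(
      step = step, reads_removed = before_reads - sum(x$counts),
      otus_removed = before_rich - richness(x), stringsAsFactors = FALSE))
  }
  keep <- rowSums(x$counts) > 0
  x$counts <- x$counts[keep, , drop = FALSE]
  if (!is.null(x$taxonomy)) x$taxonomy <- x$taxonomy[keep]
  attr(x, "filter_log") <- log
  x
}
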