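#' Assign each OTU to a size class
#'
#' Estimates a specimen size class per OTU from the individually sequenced
#' size-fraction libraries: for every class the OTU's relative read
#' abundances are summed across all source samples ("combined"), and the
#' class attaining the highest combined abundance is selected. An OTU with no
#' reads in any fraction library — e.g. one detected only in pooled lysates —
#' is labelled `unassigned`. Argmax ties are broken towards the smaller size
#' class, deterministically, and flagged.
#'
#' @param x an [otu_table] whose fraction libraries (category `"fraction"`,
#'   typically replicate-merged and quality-filtered) are used as evidence;
#'   other columns are ignored. At most one library per (source, fraction) is
#'   allowed.
#' @return object of class `size_class_assignment`: a data frame with one
#'   row per OTU — `otu_id`, `class` (factor S, M, L, XL, unassigned), the
#'   per-class combined relative abundances `S`, `M`, `L`, `XL` (the evidence
#'   vector), and `tie`.
#' @export
assign_size_classes <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  s <- x$samples[x$samples$category == "fraction", , drop = FALSE]
  if (nrow(s) == 0) stop("no fraction libraries in the table")
  if (anyDuplicated(paste(s$source, s$fraction))) {
    stop("duplicate (source, fraction) libraries; merge replicates first")
  }
  evidence <- matrix(0, nrow = nrow(x$counts), ncol = length(FRACTIONS),
                     dimnames = list(rownames(x$counts), FRACTIONS))
  for (i in seq_len(nrow(s))) {
    rel <- rel_abundance(x$counts[, s$sample_id[i]])
    evidence[, s$fraction[i]] <- evidence[, s$fraction[i]] + rel
  }
  n <- nrow(evidence)
  class <- character(n)
  tie <- logical(n)
  for (i in seq_len(n)) {
    e <- evidence[i, ]
    if (all(e == 0)) {
      class[i] <- "unassigned"
    } else {
      best <- which(e == max(e))  # FRACTIONS is ordered small to large
      class[i] <- FRACTIONS[best[1]]
      tie[i] <- length(best) > 1
    }
  }
  structure(data.frame(otu_id = rownames(evidence),
                       class = factor(class, levels = c(FRACTIONS, "unassigned")),
                       evidence, tie = tie,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("size_class_assignment", "data.frame"))
}

#' @export
print.size_class_assignment <- function(x, ...) {
  cat(sprintf("size_class_assignment: %d OTUs\n", nrow(x)))
  print(table(x$class))
  invisible(x)
}

#' @export
plot.size_class_assignment <- function(x, ...) {
  sp <- size_class_spectrum(x)
  graphics::barplot(sp, ylab = "% of OTUs", xlab = "size class", ...)
  invisible(x)
}

#' Size-class spectrum
#'
#' Percentage of OTUs assigned to each size class, including the unassigned
#' share; the denominator is all OTUs, so the percentages sum to 100.
#'
#' @param assignment a [size_class_assignment].
#' @return named numeric vector over S, M, L, XL, unassigned, in percent.
#' @export
size_class_spectrum <- function(assignment) {
  stopifnot(inherits(assignment, "size_class_assignment"),
            nrow(assignment) > 0)
  tab <- table(assignment$class)
  stats::setNames(100 * as.numeric(tab) / nrow(assignment), names(tab))
}

#' Fraction-sharing histogram
#'
#' Counts OTUs by the number of size fractions they are detected in (a
#' nonzero filtered count in any source sample's library of that fraction).
#'
#' @param x an [otu_table] with fraction libraries.
#' @return named integer vector: count of OTUs present in exactly k
#'   fractions, k = 1..4. The counts sum to the number of OTUs detected in
#'   at least one fraction.
#' @export
fraction_sharing <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  s <- x$samples[x$samples$category == "fraction", , drop = FALSE]
  if (nrow(s) == 0) stop("no fraction libraries in the table")
  present <- vapply(FRACTIONS, function(f) {
    ids <- s$sample_id[s$fraction == f]
    if (!length(ids)) return(rep(FALSE, nrow(x$counts)))
    rowSums(x$counts[, ids, drop = FALSE]) > 0
  }, logical(nrow(x$counts)))
  k <- rowSums(present)
  stats::setNames(vapply(1:4, function(i) sum(k == i), 0L), paste0("k", 1:4))
}

#' Pairwise sample dissimilarity
#'
#' Jaccard dissimilarity (`1 - |A n B| / |A u B|`) on presence/absence, or
#' Bray–Curtis (`sum |p_i - q_i| / sum (p_i + q_i)`) on per-sample relative
#' abundances.
#'
#' @param x an [otu_table], or a numeric matrix of counts/abundances with
#'   OTUs in rows and samples in columns.
#' @param metric `"jaccard"` or `"bray_curtis"`.
#' @return object of class `dissimilarity_matrix`: a symmetric numeric matrix
#'   in \[0,1\] with zero diagonal and attribute `"metric"`.
#' @export
dissimilarity <- function(x, metric = c("jaccard", "bray_curtis")) {
  metric <- match.arg(metric)
  m <- if (inherits(x, "otu_table")) x$counts else as.matrix(x)
  if (ncol(m) < 2) stop("need at least two samples")
  zero <- colSums(m) == 0
  if (any(zero)) {
    stop("sample(s) with zero total: ",
         paste(colnames(m)[zero], collapse = ", "))
  }
  comm <- t(apply(m, 2, rel_abundance))  # samples x OTUs, rows sum to 1
  rownames(comm) <- colnames(m)
  d <- if (metric == "jaccard") {
    vegan::vegdist(comm > 0, method = "jaccard", binary = TRUE)
  } else {
    vegan::vegdist(comm, method = "bray")
  }
  out <- as.matrix(d)
  structure(out, metric = metric, class = c("dissimilarity_matrix", "matrix",
                                            "array"))
}

#' Hierarchical clustering of a dissimilarity matrix
#'
#' Agglomerative clustering of samples (UPGMA by default; average linkage
#' guarantees monotone merge heights for these metrics in practice), with the
#' tree also serialised as a Newick string.
#'
#' @param m a [dissimilarity_matrix] (or plain symmetric matrix).
#' @param linkage linkage method passed to [stats::hclust()] (default
#'   `"average"`).
#' @return an [stats::hclust] object with attribute `"newick"`.
#' @export
cluster_dendrogram <- function(m, linkage = "average") {
  if (nrow(m) < 2) stop("need at least two samples to cluster")
  hc <- stats::hclust(stats::as.dist(m), method = linkage)
  attr(hc, "newick") <- dendrogram_newick(hc)
  hc
}

#' Serialise a dendrogram as Newick
#'
#' @param hc an [stats::hclust] object.
#' @return single Newick string.
#' @export
dendrogram_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}
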