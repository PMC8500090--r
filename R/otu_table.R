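#' @keywords internal
"_PACKAGE"

# Canonical ordering of size fractions, smallest first. Used for tie-breaking
# in size-class assignment and for validating metadata.
FRACTIONS <- c("S", "M", "L", "XL")
STRATEGIES <- c("g", "equ", "invg", "fibo", "log", "4x")
CATEGORIES <- c("fraction", "pooled_lysate", "negative_control")

#' Construct an OTU table
#'
#' The central data container of the package: a non-negative integer read-count
#' matrix with OTUs as rows and sequencing libraries (samples) as columns,
#' together with per-sample metadata and optional per-OTU taxonomy strings.
#'
#' @param counts numeric matrix of read counts, OTUs in rows and samples in
#'   columns; all entries must be non-negative whole numbers. Row names are
#'   the OTU identifiers, column names the sample identifiers.
#' @param samples optional data frame of per-sample metadata with columns
#'   `sample_id`, `source`, `category`, `fraction`, `strategy`, `replicate`,
#'   one row per column of `counts` (matched by `sample_id`). If `NULL`, the
#'   metadata are inferred from the column names via [parse_sample_ids()].
#' @param taxonomy optional character vector of taxonomy strings, one per OTU.
#'
#' @details Sample categories: `"fraction"` libraries carry a size fraction
#'   label (one of S, M, L, XL, smallest to largest); `"pooled_lysate"`
#'   libraries carry a pooling-strategy label (g, equ, invg, fibo, log, 4x or
#'   a custom name); `"negative_control"` libraries carry neither.
#'
#' @return An object of class `otu_table`: a list with elements `counts`,
#'   `samples` and `taxonomy`.
#' @seealso [read_otu_table()], [write_otu_table()]
#' @export
#' @examples
#' m <- matrix(c(10L, 0L, 5L, 2L), 2, 2,
#'             dimnames = list(c("OTU_1", "OTU_2"), c("L1_S_r1", "L1_S_r2")))
#' otu_table(m)
otu_table <- function(counts, samples = NULL, taxonomy = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts))) {
    if (nrow(counts) > 0) stop("counts must have row names (OTU ids)")
    dimnames(counts) <- list(character(0), colnames(counts))
  }
  if (ncol(counts) > 0 && is.null(colnames(counts))) {
    stop("counts must have column names (sample ids)")
  }
  if (is.null(samples)) {
    samples <- parse_sample_ids(colnames(counts))
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  x <- structure(list(counts = counts, samples = samples, taxonomy = taxonomy),
                 class = "otu_table")
  validate_otu_table(x)
  x
}

validate_otu_table <- function(x) {
  counts <- x$counts
  if (anyNA(counts)) stop("counts contain NA")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at OTU '%s', sample '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  if (any(counts != floor(counts))) {
    bad <- which(counts != floor(counts), arr.ind = TRUE)[1, ]
    stop(sprintf("non-integral count at OTU '%s', sample '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  if (anyDuplicated(rownames(counts))) {
    dup <- unique(rownames(counts)[duplicated(rownames(counts))])
    stop("duplicated OTU ids: ", paste(dup, collapse = ", "))
  }
  if (anyDuplicated(colnames(counts))) {
    dup <- unique(colnames(counts)[duplicated(colnames(counts))])
    stop("duplicated sample ids: ", paste(dup, collapse = ", "))
  }
  s <- x$samples
  need <- c("sample_id", "source", "category", "fraction", "strategy", "replicate")
  miss <- setdiff(need, names(s))
  if (length(miss)) stop("sample metadata lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(s) != ncol(counts) || !setequal(s$sample_id, colnames(counts))) {
    stop("sample metadata does not match count matrix columns")
  }
  if (!all(s$category %in% CATEGORIES)) {
    stop("unknown sample category: ",
         paste(setdiff(unique(s$category), CATEGORIES), collapse = ", "))
  }
  isfr <- s$category == "fraction"
  if (any(isfr & (is.na(s$fraction) | !(s$fraction %in% FRACTIONS)))) {
    stop("fraction libraries must carry a fraction label in {S, M, L, XL}")
  }
  ispl <- s$category == "pooled_lysate"
  if (any(ispl & is.na(s$strategy))) {
    stop("pooled_lysate libraries must carry a strategy label")
  }
  isnc <- s$category == "negative_control"
  if (any(isnc & (!is.na(s$fraction) | !is.na(s$strategy)))) {
    stop("negative controls must carry neither fraction nor strategy")
  }
  if (!is.null(x$taxonomy) && length(x$taxonomy) != nrow(counts)) {
    stop("taxonomy length does not match the number of OTUs")
  }
  invisible(x)
}

#' Infer sample metadata from sample identifiers
#'
#' Fallback convention for sample names that encode their own metadata, as is
#' common in metabarcoding exports: `"<source>_<label>_r<replicate>"`, e.g.
#' `"L1_S_r1"` (size-fraction library), `"L2_equ_r2"` (pooled-lysate library).
#' Names starting with `NC` or `neg` (case-insensitive) are treated as
#' negative controls. A `<label>` in `{S, M, L, XL}` marks a fraction library;
#' any other label marks a pooled-lysate library with that strategy name.
#'
#' @param sample_ids character vector of sample identifiers.
#' @return data frame with columns `sample_id`, `source`, `category`,
#'   `fraction`, `strategy`, `replicate`.
#' @export
parse_sample_ids <- function(sample_ids) {
  n <- length(sample_ids)
  out <- data.frame(sample_id = as.character(sample_ids),
                    source = NA_character_, category = NA_character_,
                    fraction = NA_character_, strategy = NA_character_,
                    replicate = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    id <- sample_ids[i]
    if (grepl("^(nc|neg)", id, ignore.case = TRUE)) {
      out$category[i] <- "negative_control"
      rep <- sub(".*?([0-9]+)$", "\\1", id)
      if (grepl("^[0-9]+$", rep)) out$replicate[i] <- as.integer(rep)
      next
    }
    parts <- strsplit(id, "_", fixed = TRUE)[[1]]
    if (length(parts) < 2) {
      stop(sprintf("cannot parse sample id '%s'; supply metadata explicitly", id))
    }
    out$source[i] <- parts[1]
    label <- parts[2]
    if (length(parts) >= 3 && grepl("^r[0-9]+$", parts[3])) {
      out$replicate[i] <- as.integer(sub("^r", "", parts[3]))
    }
    if (label %in% FRACTIONS) {
      out$category[i] <- "fraction"
      out$fraction[i] <- label
    } else {
      out$category[i] <- "pooled_lysate"
      out$strategy[i] <- label
    }
  }
  out
}

#' Read an OTU table from a tab-delimited file
#'
#' Expects a UTF-8, tab-delimited file with a header row: first column OTU
#' identifiers, remaining columns integer read counts per sample, and an
#' optional trailing `taxonomy` column. Sample metadata come from a separate
#' tab-delimited file (columns `sample_id`, `source`, `category`, `fraction`,
#' `strategy`, `replicate`), or are parsed from the sample names themselves
#' when `metadata` is `NULL` (see [parse_sample_ids()]).
#'
#' @param path path to the OTU-table TSV.
#' @param metadata optional path to a metadata TSV, or a data frame.
#' @param col_map optional named character vector renaming metadata columns,
#'   e.g. `c(sample = "sample_id")` when the file uses non-standard headers.
#' @return an [otu_table].
#' @export
read_otu_table <- function(path, metadata = NULL, col_map = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          fileEncoding = "UTF-8")
  if (ncol(df) < 1) stop("OTU table file has no columns: ", path)
  if (anyDuplicated(names(df))) {
    dup <- unique(names(df)[duplicated(names(df))])
    stop("duplicated sample columns in ", path, ": ", paste(dup, collapse = ", "))
  }
  otu_ids <- as.character(df[[1]])
  df <- df[, -1, drop = FALSE]
  taxonomy <- NULL
  if (ncol(df) > 0 && names(df)[ncol(df)] == "taxonomy") {
    taxonomy <- as.character(df[[ncol(df)]])
    df <- df[, -ncol(df), drop = FALSE]
  }
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (anyNA(v) && !anyNA(df[[j]])) {
      bad <- which(is.na(v))[1]
      stop(sprintf("non-numeric count in column '%s', row %d of %s",
                   names(df)[j], bad, path))
    }
    df[[j]] <- v
  }
  counts <- as.matrix(df)
  rownames(counts) <- otu_ids
  if (!is.null(metadata)) {
    meta <- if (is.character(metadata)) {
      utils::read.delim(metadata, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE, fileEncoding = "UTF-8")
    } else {
      as.data.frame(metadata, stringsAsFactors = FALSE)
    }
    if (!is.null(col_map)) {
      for (std in names(col_map)) {
        names(meta)[names(meta) == col_map[[std]]] <- std
      }
    }
    for (col in c("fraction", "strategy")) {
      if (!col %in% names(meta)) meta[[col]] <- NA_character_
      meta[[col]][!is.na(meta[[col]]) & meta[[col]] == ""] <- NA
    }
    if (!"replicate" %in% names(meta)) meta$replicate <- NA_integer_
    missing <- setdiff(colnames(counts), meta$sample_id)
    if (length(missing)) {
      stop("metadata lacks sample ids: ", paste(missing, collapse = ", "))
    }
    meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
    rownames(meta) <- NULL
    return(otu_table(counts, samples = meta, taxonomy = taxonomy))
  }
  otu_table(counts, taxonomy = taxonomy)
}

#' Write an OTU table to a tab-delimited file
#'
#' Inverse of [read_otu_table()]: writes the counts (and, if present, a
#' trailing `taxonomy` column) so that re-reading yields an identical table.
#'
#' @param x an [otu_table].
#' @param path output path for the OTU-table TSV.
#' @param metadata_path optional path; when given, the sample metadata are
#'   written there as a TSV.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(x, path, metadata_path = NULL) {
  stopifnot(inherits(x, "otu_table"))
  ids <- rownames(x$counts)
  if (is.null(ids)) ids <- character(0)  # 0-row matrices may drop dimnames
  df <- data.frame(OTU_ID = ids, x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(x$taxonomy)) df$taxonomy <- x$taxonomy
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  if (!is.null(metadata_path)) {
    utils::write.table(x$samples, metadata_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d OTUs x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  tab <- table(factor(x$samples$category, levels = CATEGORIES))
  cat(sprintf("  fraction libraries: %d, pooled lysates: %d, negative controls: %d\n",
              tab[["fraction"]], tab[["pooled_lysate"]], tab[["negative_control"]]))
  cat(sprintf("  total reads: %s\n", format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' Subset the samples of an OTU table
#'
#' @param x an [otu_table].
#' @param sample_ids character vector of sample ids to keep, in order.
#' @param drop_empty_otus drop OTUs whose counts are all zero after
#'   subsetting.
#' @return an [otu_table].
#' @export
subset_samples <- function(x, sample_ids, drop_empty_otus = FALSE) {
  stopifnot(inherits(x, "otu_table"))
  missing <- setdiff(sample_ids, colnames(x$counts))
  if (length(missing)) stop("unknown sample ids: ", paste(missing, collapse = ", "))
  counts <- x$counts[, sample_ids, drop = FALSE]
  samples <- x$samples[match(sample_ids, x$samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  taxonomy <- x$taxonomy
  if (drop_empty_otus) {
    keep <- rowSums(counts) > 0
    counts <- counts[keep, , drop = FALSE]
    if (!is.null(taxonomy)) taxonomy <- taxonomy[keep]
  }
  otu_table(counts, samples = samples, taxonomy = taxonomy)
}

# relative abundance of one column; all-zero columns stay zero
rel_abundance <- function(v) {
  tot <- sum(v)
  if (tot == 0) return(v)
  v / tot
}
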