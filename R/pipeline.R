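#' Sum extraction replicates without filtering
#'
#' Prepares tables in "direct pooling" mode: each replicate pair is summed
#' into one column, with no replicate-consistency requirement and no
#' abundance threshold. This is the upstream preparation used for
#' depth-rarefaction curves; contrast with [quality_filter()].
#'
#' @param x an [otu_table].
#' @return an [otu_table] with one column per replicate pair (negative
#'   controls dropped; unpaired samples kept as-is).
#' @export
sum_replicates <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  keep <- x$samples$sample_id[x$samples$category != "negative_control"]
  x <- subset_samples(x, keep)
  pairing <- replicate_pairing(x)
  cols <- list(); meta <- list()
  for (i in seq_len(nrow(pairing))) {
    lab <- ifelse(pairing$category[i] == "fraction",
                  pairing$fraction[i], pairing$strategy[i])
    id <- paste(pairing$source[i], lab, sep = "_")
    cols[[id]] <- x$counts[, pairing$rep1[i]] + x$counts[, pairing$rep2[i]]
    meta[[id]] <- .meta_row(id, pairing$source[i], pairing$category[i],
                            fraction = pairing$fraction[i],
                            strategy = pairing$strategy[i])
  }
  unpaired <- setdiff(keep, c(pairing$rep1, pairing$rep2))
  for (id in unpaired) {
    cols[[id]] <- x$counts[, id]
    meta[[id]] <- x$samples[x$samples$sample_id == id, , drop = FALSE]
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- rownames(x$counts)
  samples <- do.call(rbind, meta)
  rownames(samples) <- NULL
  otu_table(counts, samples = samples, taxonomy = x$taxonomy)
}

# named list fraction -> single-column count vector for one source, from a
# replicate-merged table
.fraction_columns <- function(x, source) {
  s <- x$samples[x$samples$category == "fraction" &
                   x$samples$source == source, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(s))) {
    out[[s$fraction[i]]] <- x$counts[, s$sample_id[i]]
  }
  out
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage on one configuration: simulate a scenario (or
#' load an OTU table and metadata from disk), quality-filter, pool the size
#' fractions (two-fraction sweep and equal quarter-depth pool per source
#' sample), compute depth-rarefaction curves and depth-equivalence factors
#' per strategy, assign size classes and summarise (spectrum, fraction
#' sharing, Jaccard and Bray-Curtis dissimilarity with dendrograms). All
#' stage outputs are TSV files under `output_dir`, plus a manifest with MD5
#' digests; identical configuration and seed give byte-identical outputs.
#'
#' @param config a list, or path to a YAML file, with elements:
#'   \describe{
#'     \item{seed}{integer scenario seed (default 1).}
#'     \item{output_dir}{output directory (created if needed).}
#'     \item{scenario}{named overrides passed to [sim_config()]; used when no
#'       `input` is given.}
#'     \item{input}{optional list with `table`, `metadata` and `weights`
#'       paths for running on real data instead of a simulation.}
#'     \item{filter}{list: `threshold_pct` (default 0.01), `skip_negatives`.}
#'     \item{sweep}{list: `step_pct`, `depth`, `threshold_pct`.}
#'     \item{rarefaction}{list: `mode` ("fig3" or "filtered"), `grid`
#'       (`from`, `to`, `n`), `reference`, `reference_depth`.}
#'   }
#' @return invisibly, the run manifest: a list with `outputs` (data frame of
#'   files and MD5 digests), `seed`, `parameters` and key results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1
  out_dir <- config$output_dir %||% stop("config$output_dir is required")
  fcfg <- config$filter %||% list()
  scfg <- config$sweep %||% list()
  rcfg <- config$rarefaction %||% list()

  # fail fast: resolve all inputs before computing anything
  if (!is.null(config$input)) {
    paths <- unlist(config$input)
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      stop("input file(s) not found: ", paste(missing, collapse = ", "))
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character()
  emit <- function(obj, name) {
    path <- file.path(out_dir, name)
    if (inherits(obj, "otu_table")) {
      write_otu_table(obj, path, metadata_path = sub("\\.tsv$", "_meta.tsv", path))
      outputs <<- c(outputs, path, sub("\\.tsv$", "_meta.tsv", path))
    } else if (is.data.frame(obj) || is.matrix(obj)) {
      utils::write.table(obj, path, sep = "\t", quote = FALSE,
                         row.names = is.matrix(obj))
      outputs <<- c(outputs, path)
    } else {
      writeLines(as.character(obj), path)
      outputs <<- c(outputs, path)
    }
  }

  # stage 1: data
  if (is.null(config$input)) {
    sim_cfg <- do.call(sim_config, config$scenario %||% list())
    scen <- simulate_scenario(sim_cfg, seed = seed)
    table <- scen$table
    weights <- scen$weights
    emit(table, "raw_table.tsv")
    emit(weights, "fraction_weights.tsv")
    emit(scen$truth, "ground_truth.tsv")
  } else {
    table <- read_otu_table(config$input$table, metadata = config$input$metadata)
    weights <- utils::read.delim(config$input$weights, stringsAsFactors = FALSE)
  }

  # stage 2: quality filtering
  filtered <- quality_filter(table,
                             threshold_pct = fcfg$threshold_pct %||% 0.01,
                             skip_negatives = isTRUE(fcfg$skip_negatives))
  emit(filtered, "filtered_table.tsv")
  emit(attr(filtered, "filter_log"), "filter_log.tsv")

  sources <- sort(unique(stats::na.omit(filtered$samples$source)))

  # stage 3: pooling analyses per source
  sweep_rows <- list(); quarter <- list()
  for (src in sources) {
    fr <- .fraction_columns(filtered, src)
    if (length(fr) < 4) next
    w <- weights[weights$source == src, , drop = FALSE]
    wv <- stats::setNames(w$weight, w$fraction)
    small <- build_combined_fraction(fr$S, fr$M, wv[c("S", "M")],
                                     fractions = c("S", "M"))
    large <- build_combined_fraction(fr$L, fr$XL, wv[c("L", "XL")],
                                     fractions = c("L", "XL"))
    curve <- two_fraction_sweep(small, large,
                                step_pct = scfg$step_pct %||% 5,
                                depth = scfg$depth %||% 10000,
                                threshold_pct = scfg$threshold_pct %||% 0.01)
    sweep_rows[[src]] <- data.frame(source = src, pct_small = curve$x,
                                    richness = curve$richness)
    quarter[[src]] <- data.frame(source = src,
                                 richness = as.integer(equal_quarter_pool(fr)))
  }
  if (length(sweep_rows)) emit(do.call(rbind, sweep_rows), "two_fraction_sweep.tsv")
  if (length(quarter)) emit(do.call(rbind, quarter), "equal_quarter_pool.tsv")

  # stage 4: rarefaction per strategy
  mode <- rcfg$mode %||% "fig3"
  prepped <- if (mode == "fig3") sum_replicates(table) else filtered
  s <- prepped$samples[prepped$samples$category == "pooled_lysate", , drop = FALSE]
  grid_cfg <- rcfg$grid %||% list()
  grid <- depth_grid(grid_cfg$from %||% 500, grid_cfg$to %||% 50000,
                     grid_cfg$n %||% 19)
  factors <- list(); curve_rows <- list()
  for (src in intersect(sources, unique(s$source))) {
    ids <- s$sample_id[s$source == src]
    tabs <- lapply(stats::setNames(ids, s$strategy[s$source == src]),
                   function(id) prepped$counts[, id])
    curves <- recovery_curves(tabs, depths = grid, mode = mode)
    for (lab in names(curves)) {
      curve_rows[[paste(src, lab)]] <-
        data.frame(source = src, strategy = lab,
                   depth = curves[[lab]]$x, richness = curves[[lab]]$richness)
    }
    ref <- rcfg$reference %||% "g"
    if (ref %in% names(curves)) {
      f <- depth_equivalence_factor(curves, reference = ref,
                                    reference_depth = rcfg$reference_depth %||%
                                      max(grid))
      f$source <- src
      factors[[src]] <- f
    }
  }
  if (length(curve_rows)) emit(do.call(rbind, curve_rows), "rarefaction_curves.tsv")
  if (length(factors)) emit(do.call(rbind, factors), "depth_equivalence.tsv")

  # stage 5: community summaries
  assignment <- assign_size_classes(filtered)
  emit(as.data.frame(assignment), "size_class_assignment.tsv")
  emit(data.frame(class = names(size_class_spectrum(assignment)),
                  pct = as.numeric(size_class_spectrum(assignment))),
       "size_class_spectrum.tsv")
  sharing <- fraction_sharing(filtered)
  emit(data.frame(n_fractions = 1:4, otus = as.integer(sharing)),
       "fraction_sharing.tsv")
  # dissimilarity is undefined for empty libraries; compare the rest
  nonempty <- filtered$samples$sample_id[colSums(filtered$counts) > 0]
  if (length(nonempty) >= 2) {
    dtab <- subset_samples(filtered, nonempty)
    for (metric in c("jaccard", "bray_curtis")) {
      d <- dissimilarity(dtab, metric = metric)
      emit(unclass(d), paste0("dissimilarity_", metric, ".tsv"))
      emit(attr(cluster_dendrogram(d), "newick"),
           paste0("dendrogram_", metric, ".nwk"))
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("sievepool")),
    seed = seed,
    parameters = list(filter = fcfg, sweep = scfg, rarefaction = rcfg),
    outputs = data.frame(file = basename(outputs),
                         md5 = unname(tools::md5sum(outputs)),
                         stringsAsFactors = FALSE))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  summary_lines <- c(
    sprintf("sievepool run (seed %d)", seed),
    sprintf("libraries: %d, OTUs after filtering: %d",
            ncol(table$counts), nrow(filtered$counts)),
    sprintf("outputs: %d files in %s", length(outputs) + 1, out_dir))
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
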