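#' Evaluate one simulated scenario with the full analysis pipeline
#'
#' Runs the complete downstream analysis on a simulated scenario and collects
#' the study's headline quantities: post-filter OTU richness per pooling
#' strategy, the two-fraction sweep optimum, the equal quarter-depth pool
#' gain over the equ lysate, depth-equivalence factors of each strategy
#' against the dry-weight (unsorted) reference, size-class assignment
#' accuracy against the simulation's ground truth, and fraction sharing.
#'
#' @param scenario a `sim_scenario` from [simulate_scenario()], or a seed
#'   passed to it together with `config`.
#' @param config a [sim_config], used when `scenario` is a seed.
#' @param reference_depth depth at which the reference strategy's richness is
#'   matched (default 50,000 reads).
#' @param grid_n number of points on the rarefaction depth grid (default 19).
#' @return list with elements `richness` (data frame source, strategy,
#'   richness), `sweep` (data frame source, best_pct_small, best_pct_large,
#'   interior), `quarter` (data frame source, richness, equ_richness,
#'   gain_pct), `equivalence` (data frame of depth-equivalence factors per
#'   source and strategy), `assignment` (data frame otu_id, class,
#'   true_class), `recovery_pct` (percent of detected, truth-bearing OTUs
#'   whose assigned class matches the ground truth), `sharing` (k = 1..4
#'   histogram), `spectrum` (percent of OTUs per size class).
#' @export
evaluate_scenario <- function(scenario, config = sim_config(),
                              reference_depth = 50000, grid_n = 19) {
  if (!inherits(scenario, "sim_scenario")) {
    scenario <- simulate_scenario(config, seed = scenario)
  }
  filtered <- quality_filter(scenario$table)
  s <- filtered$samples
  sources <- sort(unique(stats::na.omit(s$source)))

  # post-filter richness per pooled-lysate library
  lys <- s[s$category == "pooled_lysate", , drop = FALSE]
  richness <- data.frame(
    source = lys$source, strategy = lys$strategy,
    richness = vapply(lys$sample_id,
                      function(id) sum(filtered$counts[, id] > 0), 0L),
    row.names = NULL, stringsAsFactors = FALSE)

  sweep_rows <- list(); quarter_rows <- list()
  for (src in sources) {
    fr <- .fraction_columns(filtered, src)
    if (length(fr) < 4) next
    w <- scenario$weights[scenario$weights$source == src, , drop = FALSE]
    wv <- stats::setNames(w$weight, w$fraction)
    small <- build_combined_fraction(fr$S, fr$M, wv[c("S", "M")], c("S", "M"))
    large <- build_combined_fraction(fr$L, fr$XL, wv[c("L", "XL")], c("L", "XL"))
    curve <- two_fraction_sweep(small, large)
    best <- curve$x[which.max(curve$richness)]
    sweep_rows[[src]] <- data.frame(
      source = src, best_pct_small = best, best_pct_large = 100 - best,
      interior = best > 0 & best < 100, stringsAsFactors = FALSE)
    q <- as.integer(equal_quarter_pool(fr))
    equ_rich <- richness$richness[richness$source == src &
                                    richness$strategy == "equ"]
    quarter_rows[[src]] <- data.frame(
      source = src, richness = q, equ_richness = equ_rich,
      gain_pct = 100 * (q - equ_rich) / equ_rich, stringsAsFactors = FALSE)
  }

  # depth rarefaction in direct-pooling mode, per source
  prepped <- sum_replicates(scenario$table)
  ps <- prepped$samples[prepped$samples$category == "pooled_lysate", , drop = FALSE]
  grid <- depth_grid(n = grid_n)
  equiv <- list()
  for (src in sources) {
    ids <- ps$sample_id[ps$source == src]
    tabs <- lapply(stats::setNames(ids, ps$strategy[ps$source == src]),
                   function(id) prepped$counts[, id])
    curves <- recovery_curves(tabs, depths = grid, mode = "fig3")
    if (!"g" %in% names(curves)) next
    f <- depth_equivalence_factor(curves, reference = "g",
                                  reference_depth = reference_depth)
    f$source <- src
    equiv[[src]] <- f
  }

  assignment <- assign_size_classes(filtered)
  merged <- merge(assignment[, c("otu_id", "class")],
                  scenario$truth[, c("otu_id", "true_class")], by = "otu_id")
  scored <- merged[merged$class != "unassigned" & !is.na(merged$true_class), ]
  recovery_pct <- if (nrow(scored)) {
    100 * mean(as.character(scored$class) == scored$true_class)
  } else {
    NA_real_
  }

  list(richness = richness,
       sweep = do.call(rbind, sweep_rows),
       quarter = do.call(rbind, quarter_rows),
       equivalence = do.call(rbind, equiv),
       assignment = merged,
       recovery_pct = recovery_pct,
       sharing = fraction_sharing(filtered),
       spectrum = size_class_spectrum(assignment))
}

#' Replicate the simulated study over many seeds
#'
#' Repeats [simulate_scenario()] + [evaluate_scenario()] over consecutive
#' seeds and aggregates the per-seed quantities used by the directional
#' analyses: mean post-filter richness per strategy, the sweep optimum, the
#' equal quarter-depth gain, the depth-equivalence factor of the
#' small-favouring strategies over the unsorted reference, and the
#' size-class recovery rate.
#'
#' @param n_seeds number of independent scenarios (default 20).
#' @param config a [sim_config] applied to every scenario.
#' @param seed base seed; scenario i uses `seed + i - 1`.
#' @param ... passed to [evaluate_scenario()].
#' @return data frame with one row per seed: mean richness per strategy
#'   (columns named by strategy), `best_pct_small`, `sweep_interior`
#'   (fraction of sources with an interior optimum), `quarter_gain_pct`,
#'   `factor_small_favouring` (mean depth-equivalence factor of invg, fibo,
#'   4x and log), `recovery_pct`, `pct_single_fraction`, and the size-class
#'   spectrum shares `pct_S` .. `pct_unassigned`.
#' @export
replicate_study <- function(n_seeds = 20, config = sim_config(), seed = 1,
                            ...) {
  small_fav <- c("invg", "fibo", "4x", "log")
  rows <- lapply(seq_len(n_seeds), function(i) {
    ev <- evaluate_scenario(simulate_scenario(config, seed = seed + i - 1), ...)
    rich <- tapply(ev$richness$richness, ev$richness$strategy, mean)
    eq <- ev$equivalence[ev$equivalence$strategy %in% small_fav, , drop = FALSE]
    data.frame(seed = seed + i - 1,
               t(rich),
               best_pct_small = mean(ev$sweep$best_pct_small),
               sweep_interior = mean(ev$sweep$interior),
               quarter_gain_pct = mean(ev$quarter$gain_pct),
               factor_small_favouring = mean(eq$factor, na.rm = TRUE),
               recovery_pct = ev$recovery_pct,
               pct_single_fraction = 100 * ev$sharing[["k1"]] / sum(ev$sharing),
               pct_S = ev$spectrum[["S"]], pct_M = ev$spectrum[["M"]],
               pct_L = ev$spectrum[["L"]], pct_XL = ev$spectrum[["XL"]],
               pct_unassigned = ev$spectrum[["unassigned"]],
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
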