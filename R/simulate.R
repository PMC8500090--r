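#' Configure the bulk-sample simulator
#'
#' Collects every knob of the forward simulation of a size-structured
#' arthropod bulk sample: community composition, body sizes and allometric
#' weights, sieving into the four size fractions, fragment carryover between
#' fractions, and sequencing (read depth, per-species primer bias, extraction
#' replicates, negative controls).
#'
#' @param n_species number of species in the regional pool (one OTU each).
#' @param mu_a,sigma_a log-mean and log-sd of the lognormal rank-abundance
#'   model; a species' expected specimen count per bulk sample is
#'   `Lognormal(mu_a, sigma_a)` and its realised count Poisson around that.
#' @param mu_L,sigma_L log-mean and log-sd of per-species mean body length
#'   (mm). Defaults centre the community on small specimens (median 2.5 mm)
#'   with a long tail of large ones, the typical shape of a Malaise-trap
#'   catch.
#' @param length_cv within-species log-sd of individual body length.
#' @param length_bounds truncation bounds for body length, mm.
#' @param allometry_a,allometry_b length-weight allometry
#'   `weight_mg = a * length_mm^b`; defaults 0.0305 and 2.62, a widely used
#'   general-insect fit.
#' @param mesh_diameters_mm strictly decreasing sieve-hole diameters; the
#'   default `c(8, 4, 2)` yields fractions XL (> 8 mm), L (> 4 mm),
#'   M (> 2 mm) and S (fell through all meshes).
#' @param retention_k effective-width factor: a specimen is retained by mesh
#'   `m` when `retention_k * body_length >= m`. Round holes retain by body
#'   cross-section, not length, hence the default 0.5.
#' @param carryover_prob probability that a specimen retained above the
#'   smallest fraction sheds a fragment (broken-off legs, attached small
#'   material) into a smaller fraction.
#' @param carryover_mass_frac fraction of the specimen's weight moved into
#'   that fragment.
#' @param bias_sigma sd of per-species log10 amplification efficiency (primer
#'   bias); fixed per species across all libraries.
#' @param depth reads per sequenced library.
#' @param n_replicates extraction replicates per library.
#' @param n_negatives number of negative-control libraries per scenario.
#' @param contamination_lambda expected stray reads per OTU per negative
#'   control (Poisson).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_species = 300,
                       mu_a = 1.5, sigma_a = 1.2,
                       mu_L = log(2.5), sigma_L = 0.9,
                       length_cv = 0.1, length_bounds = c(0.5, 30),
                       allometry_a = 0.0305, allometry_b = 2.62,
                       mesh_diameters_mm = c(8, 4, 2), retention_k = 0.5,
                       carryover_prob = 0.05, carryover_mass_frac = 0.02,
                       bias_sigma = 0.5,
                       depth = 10000, n_replicates = 2, n_negatives = 9,
                       contamination_lambda = 0.05) {
  cfg <- as.list(environment())
  if (cfg$n_species <= 0) stop("n_species must be positive")
  if (any(diff(cfg$mesh_diameters_mm) >= 0)) {
    stop("mesh_diameters_mm must be strictly decreasing")
  }
  probs <- c(cfg$carryover_prob, cfg$carryover_mass_frac)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$depth < 1) stop("depth must be >= 1")
  if (cfg$allometry_a <= 0) stop("allometry_a must be positive")
  if (cfg$contamination_lambda < 0) stop("contamination_lambda must be >= 0")
  if (length(cfg$mesh_diameters_mm) != 3) {
    stop("exactly three meshes are required for the four fractions S/M/L/XL")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: %d species, depth %d, %d replicates, ",
                     "%d negatives\n  meshes %s mm, bias_sigma %.2f, ",
                     "carryover %.2f x %.2f\n"),
              x$n_species, x$depth, x$n_replicates, x$n_negatives,
              paste(x$mesh_diameters_mm, collapse = "/"), x$bias_sigma,
              x$carryover_prob, x$carryover_mass_frac))
  invisible(x)
}

#' Draw the regional species pool
#'
#' Draws the species-level properties shared by all bulk samples of a
#' scenario: expected abundance (lognormal rank-abundance), mean body length
#' and amplification efficiency (`10^N(0, bias_sigma)`). Uses the current RNG
#' stream.
#'
#' @param config a [sim_config].
#' @return data frame with columns `otu_id`, `lambda`, `mean_length_mm`,
#'   `efficiency`.
#' @export
draw_species_pool <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_species
  data.frame(
    otu_id = sprintf("OTU_%04d", seq_len(n)),
    lambda = stats::rlnorm(n, config$mu_a, config$sigma_a),
    mean_length_mm = pmin(pmax(stats::rlnorm(n, config$mu_L, config$sigma_L),
                               config$length_bounds[1]),
                          config$length_bounds[2]),
    efficiency = 10^stats::rnorm(n, 0, config$bias_sigma),
    stringsAsFactors = FALSE)
}

#' Draw one bulk-sample community
#'
#' Realises the specimens of a single bulk sample: per-species counts are
#' Poisson around the pool's expected abundances, individual body lengths are
#' lognormal around the species mean (truncated to the configured bounds) and
#' dry weights follow the allometry `a * length^b` (mg).
#'
#' @param config a [sim_config].
#' @param seed optional integer; when given, [set.seed()] is called first.
#'   When `NULL` the current RNG stream is used (so several communities can
#'   be drawn reproducibly from one scenario seed).
#' @param pool optional species pool from [draw_species_pool()]; drawn fresh
#'   when `NULL`.
#' @param source bulk-sample label attached to the specimens (e.g. `"L1"`).
#' @return a `specimen_set`: data frame with columns `species_id`,
#'   `body_length_mm`, `dry_weight_mg`, `fraction` (NA until sieving) and
#'   `is_fragment`; attributes `"pool"` and `"source"`.
#' @export
draw_community <- function(config, seed = NULL, pool = NULL, source = "L1") {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(pool)) pool <- draw_species_pool(config)
  for (try in 1:100) {
    counts <- stats::rpois(nrow(pool), pool$lambda)
    if (sum(counts) > 0) break
  }
  if (sum(counts) == 0) stop("community draw produced no specimens")
  idx <- rep(seq_len(nrow(pool)), counts)
  len <- stats::rlnorm(length(idx), log(pool$mean_length_mm[idx]),
                       config$length_cv)
  len <- pmin(pmax(len, config$length_bounds[1]), config$length_bounds[2])
  specimens <- data.frame(
    species_id = pool$otu_id[idx],
    body_length_mm = len,
    dry_weight_mg = config$allometry_a * len^config$allometry_b,
    fraction = NA_character_,
    is_fragment = FALSE,
    stringsAsFactors = FALSE)
  structure(specimens, pool = pool, source = source,
            class = c("specimen_set", "data.frame"))
}

# fraction label for each body length under the retention rule
.fraction_for_length <- function(length_mm, config) {
  eff <- config$retention_k * length_mm
  labels <- c("XL", "L", "M")  # aligned with descending meshes
  out <- rep("S", length(length_mm))
  for (i in rev(seq_along(config$mesh_diameters_mm))) {
    out[eff >= config$mesh_diameters_mm[i]] <- labels[i]
  }
  out
}

#' Sieve specimens into size fractions
#'
#' Assigns every specimen to the fraction of the largest mesh that retains it
#' (`retention_k * body_length >= mesh diameter`); specimens passing all
#' meshes land in S. With probability `carryover_prob` a specimen retained
#' above S additionally sheds a fragment of `carryover_mass_frac` of its
#' weight into a uniformly chosen smaller fraction, its own weight reduced
#' accordingly, so total dry weight is conserved exactly.
#'
#' The ground truth recorded alongside is computed from the intact (pre-
#' fragment) biomass: each species' true size class is the fraction holding
#' the majority of its intact biomass.
#'
#' @param specimens a `specimen_set` from [draw_community()].
#' @param config a [sim_config].
#' @param seed optional integer seed (see [draw_community()]).
#' @return the `specimen_set` with `fraction` filled in and fragment rows
#'   appended; attribute `"ground_truth"` holds a data frame (`otu_id`,
#'   `true_class`, `biomass_S/M/L/XL` in mg, `efficiency`) and attribute
#'   `"fraction_weights"` the realised post-carryover dry weight per
#'   fraction (mg).
#' @export
sieve_specimens <- function(specimens, config, seed = NULL) {
  stopifnot(inherits(specimens, "specimen_set"), inherits(config, "sim_config"))
  if (!all(is.na(specimens$fraction))) stop("specimens are already sieved")
  if (!is.null(seed)) set.seed(seed)
  pool <- attr(specimens, "pool")
  specimens$fraction <- .fraction_for_length(specimens$body_length_mm, config)

  # ground truth from intact biomass, before any fragment transfer
  biomass <- matrix(0, nrow(pool), length(FRACTIONS),
                    dimnames = list(pool$otu_id, FRACTIONS))
  agg <- stats::aggregate(dry_weight_mg ~ species_id + fraction,
                          data = specimens, FUN = sum)
  biomass[cbind(agg$species_id, agg$fraction)] <- agg$dry_weight_mg
  true_class <- apply(biomass, 1, function(b) {
    if (all(b == 0)) NA_character_ else FRACTIONS[which.max(b)]
  })
  truth <- data.frame(otu_id = pool$otu_id, true_class = true_class,
                      biomass_S = biomass[, "S"], biomass_M = biomass[, "M"],
                      biomass_L = biomass[, "L"], biomass_XL = biomass[, "XL"],
                      efficiency = pool$efficiency,
                      row.names = NULL, stringsAsFactors = FALSE)

  # fragment carryover: mass transfer into a uniformly chosen smaller fraction
  if (config$carryover_prob > 0) {
    eligible <- which(specimens$fraction != "S")
    sheds <- eligible[stats::runif(length(eligible)) < config$carryover_prob]
    if (length(sheds)) {
      frag_fraction <- vapply(specimens$fraction[sheds], function(f) {
        smaller <- FRACTIONS[seq_len(match(f, FRACTIONS) - 1)]
        if (length(smaller) == 1) smaller else sample(smaller, 1)
      }, "")
      frag_weight <- config$carryover_mass_frac * specimens$dry_weight_mg[sheds]
      frags <- data.frame(species_id = specimens$species_id[sheds],
                          body_length_mm = specimens$body_length_mm[sheds],
                          dry_weight_mg = frag_weight,
                          fraction = frag_fraction, is_fragment = TRUE,
                          stringsAsFactors = FALSE)
      specimens$dry_weight_mg[sheds] <-
        specimens$dry_weight_mg[sheds] - frag_weight
      specimens <- structure(rbind(as.data.frame(specimens), frags),
                             pool = pool, source = attr(specimens, "source"),
                             class = c("specimen_set", "data.frame"))
    }
  }
  fw <- vapply(FRACTIONS, function(f) {
    sum(specimens$dry_weight_mg[specimens$fraction == f])
  }, 0)
  attr(specimens, "ground_truth") <- truth
  attr(specimens, "fraction_weights") <- fw
  specimens
}

# per-OTU dry biomass by fraction (mg), fragments included
.fraction_biomass <- function(specimens, pool) {
  w <- matrix(0, nrow(pool), length(FRACTIONS),
              dimnames = list(pool$otu_id, FRACTIONS))
  agg <- stats::aggregate(dry_weight_mg ~ species_id + fraction,
                          data = specimens, FUN = sum)
  w[cbind(agg$species_id, agg$fraction)] <- agg$dry_weight_mg
  w
}

# per-fraction read-sampling weights: biomass x amplification efficiency
.fraction_read_weights <- function(specimens, pool) {
  .fraction_biomass(specimens, pool) * pool$efficiency
}

.meta_row <- function(sample_id, source, category, fraction = NA, strategy = NA,
                      replicate = NA) {
  data.frame(sample_id = sample_id, source = source, category = category,
             fraction = fraction, strategy = strategy,
             replicate = as.integer(replicate), stringsAsFactors = FALSE)
}

#' Sequence the individual size fractions
#'
#' Simulates the per-fraction libraries: for every fraction and extraction
#' replicate, read counts are multinomial with `depth` trials and
#' probabilities proportional to (per-species biomass in the fraction) times
#' (per-species amplification efficiency). An empty fraction yields an
#' all-zero column. One OTU per species.
#'
#' @param specimens a sieved `specimen_set`.
#' @param config a [sim_config].
#' @param seed optional integer seed.
#' @return an [otu_table] with one column per fraction and replicate, named
#'   `<source>_<fraction>_r<replicate>`.
#' @export
simulate_fraction_reads <- function(specimens, config, seed = NULL) {
  stopifnot(inherits(specimens, "specimen_set"))
  if (any(is.na(specimens$fraction))) stop("sieve the specimens first")
  if (!is.null(seed)) set.seed(seed)
  pool <- attr(specimens, "pool")
  source <- attr(specimens, "source")
  w <- .fraction_read_weights(specimens, pool)
  cols <- list(); meta <- list()
  for (f in FRACTIONS) {
    for (r in seq_len(config$n_replicates)) {
      id <- sprintf("%s_%s_r%d", source, f, r)
      cols[[id]] <- if (sum(w[, f]) == 0) {
        rep(0, nrow(pool))
      } else {
        as.numeric(stats::rmultinom(1, config$depth, w[, f]))
      }
      meta[[id]] <- .meta_row(id, source, "fraction", fraction = f,
                              replicate = r)
    }
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- pool$otu_id
  otu_table(counts, samples = do.call(rbind, meta))
}

# Mixture probabilities over OTUs for a pooled lysate. Lysate DNA composition
# within a fraction is biomass-proportional; amplification efficiency acts at
# PCR, i.e. after the lysates are mixed — this makes dry-weight-proportional
# pooling reproduce the unsorted sample's read distribution exactly. Empty
# fractions contribute nothing and the remaining shares are renormalised.
.lysate_mixture_probs <- function(specimens, scheme) {
  pool <- attr(specimens, "pool")
  b <- .fraction_biomass(specimens, pool)
  dna <- stats::setNames(numeric(nrow(pool)), pool$otu_id)
  used <- 0
  for (f in names(scheme$proportions)) {
    tot <- sum(b[, f])
    if (scheme$proportions[[f]] == 0 || tot == 0) next
    dna <- dna + scheme$proportions[[f]] * b[, f] / tot
    used <- used + scheme$proportions[[f]]
  }
  if (used == 0) stop("scheme '", scheme$name,
                      "' draws only on empty fractions")
  mix <- dna * pool$efficiency
  mix / sum(mix)
}

#' Sequence a pooled lysate
#'
#' Simulates a library made from lysates of the four fractions pooled in the
#' scheme's volume proportions. Because the lysis buffer volume tracks tissue
#' weight, the DNA concentration is the same in every lysate, so volume
#' shares weight the fractions' DNA compositions directly: the pooled
#' template carries `sum_f scheme_f *` (the OTU's biomass share within
#' fraction f), and per-species amplification efficiency multiplies that
#' template at PCR. With dry-weight-proportional shares this reproduces the
#' unsorted sample's read distribution exactly. Counts are multinomial at
#' `depth` per replicate.
#'
#' @param specimens a sieved `specimen_set`.
#' @param scheme a [pooling_scheme].
#' @param config a [sim_config].
#' @param seed optional integer seed.
#' @return an [otu_table] with one column per replicate, named
#'   `<source>_<scheme>_r<replicate>`.
#' @export
simulate_lysate_pool <- function(specimens, scheme, config, seed = NULL) {
  stopifnot(inherits(specimens, "specimen_set"),
            inherits(scheme, "pooling_scheme"))
  if (any(is.na(specimens$fraction))) stop("sieve the specimens first")
  if (!is.null(seed)) set.seed(seed)
  source <- attr(specimens, "source")
  mix <- .lysate_mixture_probs(specimens, scheme)
  cols <- list(); meta <- list()
  for (r in seq_len(config$n_replicates)) {
    id <- sprintf("%s_%s_r%d", source, scheme$name, r)
    cols[[id]] <- as.numeric(stats::rmultinom(1, config$depth, mix))
    meta[[id]] <- .meta_row(id, source, "pooled_lysate",
                            strategy = scheme$name, replicate = r)
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- names(mix)
  otu_table(counts, samples = do.call(rbind, meta))
}

#' Simulate negative-control libraries
#'
#' Stray contamination only: independent Poisson counts with mean
#' `contamination_lambda` per OTU per control.
#'
#' @param config a [sim_config].
#' @param otu_ids OTU identifiers for the rows.
#' @param seed optional integer seed.
#' @return an [otu_table] with `n_negatives` columns named `NC_1`, `NC_2`, ...
#' @export
simulate_negative_controls <- function(config, otu_ids, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(otu_ids)
  counts <- matrix(stats::rpois(n * config$n_negatives,
                                config$contamination_lambda),
                   nrow = n, ncol = config$n_negatives,
                   dimnames = list(otu_ids,
                                   paste0("NC_", seq_len(config$n_negatives))))
  meta <- do.call(rbind, lapply(seq_len(config$n_negatives), function(i) {
    .meta_row(paste0("NC_", i), NA_character_, "negative_control",
              replicate = i)
  }))
  otu_table(counts, samples = meta)
}

#' Simulate a complete sequencing scenario
#'
#' Runs the full forward simulation the analysis modules expect: one shared
#' species pool; per bulk sample a community draw, sieving (with fragment
#' carryover), the four individually sequenced fractions and the six pooled
#' lysates (g, equ, invg, fibo, 4x, log — g and invg from that sample's
#' realised fraction weights), each in `n_replicates` extraction replicates;
#' plus the negative controls. All randomness comes from the single seed.
#'
#' @param config a [sim_config].
#' @param seed integer scenario seed.
#' @param sources bulk-sample labels (default `c("L1", "L2", "L3")`).
#' @param schemes optional named list of [pooling_scheme]s to use instead of
#'   [default_schemes()].
#' @return object of class `sim_scenario`: list with `table` (one
#'   [otu_table] holding every library), `weights` (data frame `source`,
#'   `fraction`, `weight` in mg), `truth` (pool-wide ground truth: per OTU
#'   the size class holding the majority of intact biomass summed over
#'   sources, plus efficiency), `truth_by_source`, `pool`, `config`, `seed`.
#' @export
simulate_scenario <- function(config = sim_config(), seed = 1,
                              sources = c("L1", "L2", "L3"), schemes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  pool <- draw_species_pool(config)
  tabs <- list(); weights <- list(); truths <- list()
  for (src in sources) {
    spec <- draw_community(config, pool = pool, source = src)
    spec <- sieve_specimens(spec, config)
    fw <- attr(spec, "fraction_weights")
    weights[[src]] <- data.frame(source = src, fraction = FRACTIONS,
                                 weight = unname(fw[FRACTIONS]),
                                 stringsAsFactors = FALSE)
    truths[[src]] <- attr(spec, "ground_truth")
    tabs[[paste0(src, "_frac")]] <- simulate_fraction_reads(spec, config)
    sch <- if (is.null(schemes)) default_schemes(fw) else schemes
    for (s in names(sch)) {
      tabs[[paste0(src, "_", s)]] <- simulate_lysate_pool(spec, sch[[s]], config)
    }
  }
  tabs$negatives <- simulate_negative_controls(config, pool$otu_id)
  counts <- do.call(cbind, lapply(tabs, function(t) t$counts))
  samples <- do.call(rbind, lapply(tabs, function(t) t$samples))
  rownames(samples) <- NULL
  table <- otu_table(counts, samples = samples)

  # pool-wide truth: majority of intact biomass summed over sources
  bm <- Reduce(`+`, lapply(truths, function(t) {
    as.matrix(t[, paste0("biomass_", FRACTIONS)])
  }))
  true_class <- apply(bm, 1, function(b) {
    if (all(b == 0)) NA_character_ else FRACTIONS[which.max(b)]
  })
  truth <- data.frame(otu_id = pool$otu_id, true_class = true_class,
                      bm, efficiency = pool$efficiency,
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = table, weights = do.call(rbind, weights),
                 truth = truth, truth_by_source = truths, pool = pool,
                 config = config, seed = seed),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("sim_scenario (seed %d): %d species, %d libraries\n",
              x$seed, nrow(x$pool), ncol(x$table$counts)))
  invisible(x)
}
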