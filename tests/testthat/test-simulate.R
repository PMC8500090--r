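test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_species = 0), "n_species")
  expect_error(sim_config(mesh_diameters_mm = c(2, 4, 8)), "decreasing")
  expect_error(sim_config(carryover_prob = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(depth = 0), "depth")
  expect_error(sim_config(allometry_a = -1), "allometry_a")
})

test_that("community draws are deterministic given a seed", {
  cfg <- small_config()
  a <- draw_community(cfg, seed = 99)
  b <- draw_community(cfg, seed = 99)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "pool"), attr(b, "pool"))
})

test_that("dry weight follows the allometric power law", {
  cfg <- small_config()
  spec <- draw_community(cfg, seed = 3)
  # direct evaluation of weight = a * length^b as the oracle
  expect_equal(spec$dry_weight_mg,
               0.0305 * spec$body_length_mm^2.62)
  # the worked value: a 10 mm specimen weighs 0.0305 * 10^2.62 mg
  expect_equal(0.0305 * 10^2.62, 12.71452, tolerance = 1e-6)
})

test_that("a one-species pool yields specimens of a single identity", {
  spec <- draw_community(sim_config(n_species = 1), seed = 5)
  expect_identical(unique(spec$species_id), "OTU_0001")
})

test_that("sieving follows the effective-width retention rule", {
  cfg <- small_config()  # meshes 8/4/2 mm, k = 0.5
  # 1 mm at k = 0.5 passes every mesh -> S; 10 mm gives 5 >= 4 -> L
  frac <- sievepool:::.fraction_for_length(c(1, 10, 30, 5), cfg)
  expect_identical(frac, c("S", "L", "XL", "M"))
})

test_that("sieving conserves dry weight, with and without fragment carryover", {
  cfg0 <- small_config(carryover_prob = 0)
  spec <- draw_community(cfg0, seed = 11)
  sieved <- sieve_specimens(spec, cfg0, seed = 11)
  # no carryover: one row per specimen, weights untouched
  expect_identical(nrow(sieved), nrow(spec))
  expect_equal(sum(sieved$dry_weight_mg), sum(spec$dry_weight_mg))
  expect_false(any(sieved$is_fragment))

  cfg1 <- small_config(carryover_prob = 0.3)
  spec1 <- draw_community(cfg1, seed = 12)
  sieved1 <- sieve_specimens(spec1, cfg1, seed = 12)
  expect_gt(sum(sieved1$is_fragment), 0)
  expect_equal(sum(sieved1$dry_weight_mg), sum(spec1$dry_weight_mg))
  # fragments land strictly below their parent's fraction and keep its species
  frags <- sieved1[sieved1$is_fragment, ]
  expect_true(all(frags$fraction %in% c("S", "M", "L")))
  expect_true(all(frags$species_id %in% spec1$species_id))
  # realised fraction weights sum to the community total
  expect_equal(sum(attr(sieved1, "fraction_weights")),
               sum(spec1$dry_weight_mg))
})

test_that("ground truth assigns each species the fraction holding most intact biomass", {
  spec <- manual_specimens(c("OTU_A", "OTU_A", "OTU_B"),
                           weight = c(3, 1, 2),
                           fraction = rep(NA_character_, 3))
  spec$body_length_mm <- c(3, 9, 20)  # -> S, L, XL at k = 0.5
  cfg <- small_config(carryover_prob = 0)
  sieved <- sieve_specimens(spec, cfg)
  truth <- attr(sieved, "ground_truth")
  expect_identical(truth$true_class[truth$otu_id == "OTU_A"], "S")  # 3 mg beats 1 mg
  expect_identical(truth$true_class[truth$otu_id == "OTU_B"], "XL")
  expect_equal(truth$biomass_S[truth$otu_id == "OTU_A"], 3)
  expect_equal(truth$biomass_L[truth$otu_id == "OTU_A"], 1)
})

test_that("each sequenced library sums exactly to the configured depth", {
  cfg <- small_config(depth = 5000)
  spec <- sieve_specimens(draw_community(cfg, seed = 21), cfg)
  tab <- simulate_fraction_reads(spec, cfg)
  sums <- colSums(tab$counts)
  nonempty <- sums > 0
  expect_true(all(sums[nonempty] == 5000))
  # empty fractions give all-zero columns, not errors
  tiny <- manual_specimens("OTU_A", 1, "S")
  tab2 <- simulate_fraction_reads(tiny, cfg, seed = 1)
  expect_identical(unname(colSums(tab2$counts)[c("L1_XL_r1", "L1_XL_r2")]),
                   c(0, 0))
  expect_identical(unname(tab2$counts["OTU_A", "L1_S_r1"]), 5000)
})

test_that("read counts are biomass-proportional in expectation without primer bias", {
  # two species at 3:1 biomass in one fraction; multinomial expectation is
  # the oracle: mean counts over many draws within 3 standard errors
  cfg <- sim_config(n_species = 2, bias_sigma = 0, depth = 1000,
                    n_replicates = 1)
  spec <- manual_specimens(c("OTU_A", "OTU_B"), weight = c(3, 1),
                           fraction = c("S", "S"))
  n_draws <- 1000
  set.seed(31)
  counts_a <- vapply(seq_len(n_draws), function(i) {
    simulate_fraction_reads(spec, cfg)$counts["OTU_A", "L1_S_r1"]
  }, 0)
  expected <- 1000 * 0.75
  se <- sqrt(1000 * 0.75 * 0.25 / n_draws)
  expect_lt(abs(mean(counts_a) - expected), 3 * se)
})

test_that("dry-weight-proportional lysate pooling equals the unsorted sample in distribution", {
  cfg <- small_config()
  spec <- sieve_specimens(draw_community(cfg, seed = 41), cfg)
  fw <- attr(spec, "fraction_weights")
  g <- pooling_scheme("g", fw / sum(fw))
  mix <- sievepool:::.lysate_mixture_probs(spec, g)
  # the unsorted sample: biomass x efficiency over the whole community
  pool <- attr(spec, "pool")
  total_bm <- sievepool:::.fraction_biomass(spec, pool)
  unsorted <- rowSums(total_bm) * pool$efficiency
  expect_equal(mix, unsorted / sum(unsorted), tolerance = 1e-12)
})

test_that("degenerate pooling schemes collapse to their constituent fractions", {
  # scheme (1,0,0,0): identical mixture to the S fraction library
  spec <- manual_specimens(c("OTU_A", "OTU_B", "OTU_C"), weight = c(2, 1, 5),
                           fraction = c("S", "S", "L"))
  only_s <- pooling_scheme("onlyS", c(S = 1, M = 0, L = 0, XL = 0))
  mix <- sievepool:::.lysate_mixture_probs(spec, only_s)
  expect_equal(unname(mix[c("OTU_A", "OTU_B", "OTU_C")]), c(2 / 3, 1 / 3, 0))

  # equal scheme over two disjoint equal-biomass fractions: 50/50 expected
  spec2 <- manual_specimens(c("OTU_A", "OTU_B"), weight = c(4, 4),
                            fraction = c("S", "L"))
  half <- pooling_scheme("half", c(S = 0.5, M = 0, L = 0.5, XL = 0))
  mix2 <- sievepool:::.lysate_mixture_probs(spec2, half)
  expect_equal(unname(mix2), c(0.5, 0.5))

  # a scheme drawing only on empty fractions is an error
  bad <- pooling_scheme("badXL", c(S = 0, M = 0, L = 0, XL = 1))
  expect_error(sievepool:::.lysate_mixture_probs(spec2, bad), "empty fractions")
})

test_that("negative controls are Poisson contamination with the configured mean", {
  cfg0 <- small_config(contamination_lambda = 0)
  tab0 <- simulate_negative_controls(cfg0, paste0("O", 1:5), seed = 51)
  expect_true(all(tab0$counts == 0))
  expect_identical(ncol(tab0$counts), 9L)

  cfg <- small_config(contamination_lambda = 0.7, n_negatives = 100)
  tab <- simulate_negative_controls(cfg, paste0("O", 1:100), seed = 52)
  draws <- as.numeric(tab$counts)  # 10,000 Poisson draws
  se <- sqrt(0.7 / length(draws))
  expect_lt(abs(mean(draws) - 0.7), 3 * se)

  a <- simulate_negative_controls(cfg, paste0("O", 1:10), seed = 53)
  b <- simulate_negative_controls(cfg, paste0("O", 1:10), seed = 53)
  expect_identical(a$counts, b$counts)
})

test_that("a full scenario is bit-identical under one seed and well-formed", {
  cfg <- small_config()
  s1 <- simulate_scenario(cfg, seed = 61, sources = c("L1", "L2"))
  s2 <- simulate_scenario(cfg, seed = 61, sources = c("L1", "L2"))
  expect_identical(s1$table$counts, s2$table$counts)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$weights, s2$weights)

  tab <- s1$table
  expect_identical(sum(tab$samples$category == "negative_control"), 9L)
  # 4 fractions x 2 replicates x 2 sources
  expect_identical(sum(tab$samples$category == "fraction"), 16L)
  # every library either empty or at full depth
  lib_ids <- tab$samples$sample_id[tab$samples$category != "negative_control"]
  sums <- colSums(tab$counts[, lib_ids])
  expect_true(all(sums %in% c(0, cfg$depth)))
  # the six strategies appear for each source
  strategies <- unique(na.omit(tab$samples$strategy))
  expect_setequal(strategies, c("g", "equ", "invg", "fibo", "4x", "log"))
})
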