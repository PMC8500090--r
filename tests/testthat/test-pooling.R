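# Independent brute-force oracle for the two-fraction sweep: explicit
# per-OTU, per-ratio enumeration, no shared code with the implementation.
brute_force_sweep <- function(small_rel, large_rel, step = 5,
                              threshold_pct = 0.01) {
  otus <- union(names(small_rel), names(large_rel))
  ratios <- seq(0, 100, by = step)
  sapply(ratios, function(r) {
    n <- 0
    for (o in otus) {
      s <- if (o %in% names(small_rel)) small_rel[[o]] else 0
      l <- if (o %in% names(large_rel)) large_rel[[o]] else 0
      mix <- (r / 100) * s + (1 - r / 100) * l
      if (mix > 0 && mix >= threshold_pct / 100) n <- n + 1
    }
    n
  })
}

test_that("pooling-scheme construction enforces the simplex over fractions", {
  sch <- pooling_scheme("equ", c(S = 0.25, M = 0.25, L = 0.25, XL = 0.25))
  expect_s3_class(sch, "pooling_scheme")
  expect_error(pooling_scheme("x", c(S = 0.5, M = 0.6)), "sum to 1")
  expect_error(pooling_scheme("x", c(S = 1.5, M = -0.5)), "non-negative")
  expect_error(pooling_scheme("x", c(tiny = 1)), "S, M, L, XL")
})

test_that("pool_by_scheme mixes relative abundances over the OTU union", {
  # identity: a single-fraction scheme returns that fraction's composition
  tabs <- list(S = c(A = 30, B = 10), M = c(A = 5, C = 5))
  sch <- pooling_scheme("onlyS", c(S = 1, M = 0))
  p <- pool_by_scheme(tabs, sch)
  expect_equal(p$rel[c("A", "B")], c(A = 0.75, B = 0.25))
  expect_equal(sum(p$rel), 1)

  # symmetry: equal scheme over two disjoint single-OTU fractions
  sch2 <- pooling_scheme("half", c(S = 0.5, M = 0.5))
  p2 <- pool_by_scheme(list(S = c(A = 7), M = c(B = 99)), sch2)
  expect_equal(sort(unname(p2$rel)), c(0.5, 0.5))

  # hand mixture: 0.6 * {A:0.5, B:0.5} + 0.4 * {A:1} = {A:0.7, B:0.3}
  sch3 <- pooling_scheme("w", c(S = 0.6, M = 0.4))
  p3 <- pool_by_scheme(list(S = c(A = 50, B = 50), M = c(A = 10)), sch3)
  expect_equal(p3$rel[["A"]], 0.7)
  expect_equal(p3$rel[["B"]], 0.3)

  # a fraction demanded by the scheme but not supplied is a named error
  expect_error(pool_by_scheme(list(S = c(A = 1)), sch2), "absent fraction.*M")
})

test_that("pool_by_weight equals pool_by_scheme with normalised weights", {
  tabs <- list(S = c(A = 3, B = 1), M = c(A = 1, C = 1))
  set.seed(11)
  for (i in 1:5) {
    w <- runif(2, 0.1, 10)
    by_w <- pool_by_weight(tabs, c(S = w[1], M = w[2]))
    by_s <- pool_by_scheme(tabs, pooling_scheme("x", c(S = w[1], M = w[2]) / sum(w)))
    expect_equal(by_w$rel, by_s$rel)
  }
  # weights 3:1 over disjoint single-OTU fractions -> 0.75 / 0.25
  p <- pool_by_weight(list(S = c(A = 5), M = c(B = 5)), c(S = 3, M = 1))
  expect_equal(unname(p$rel[c("A", "B")]), c(0.75, 0.25))
  # a zero-weight fraction contributes nothing; all-zero weights error
  p0 <- pool_by_weight(list(S = c(A = 1), M = c(B = 1)), c(S = 1, M = 0))
  expect_equal(p0$rel[["B"]], 0)
  expect_error(pool_by_weight(list(S = c(A = 1)), c(S = 0)), "all fraction weights are zero")
})

test_that("build_combined_fraction reconstructs a weight-proportional composite", {
  # equal weights over disjoint sets: union with halved shares
  p <- build_combined_fraction(c(A = 10), c(B = 10), c(1, 1))
  expect_equal(unname(p$rel[c("A", "B")]), c(0.5, 0.5))
  # zero-weight second fraction: first profile unchanged
  p2 <- build_combined_fraction(c(A = 3, B = 1), c(C = 5), c(2, 0))
  expect_equal(p2$rel[c("A", "B")], c(A = 0.75, B = 0.25))
  expect_equal(p2$rel[["C"]], 0)
  # 3-OTU fixture, weights 2:1: hand-computed shares
  # 2/3 * {A:0.5, B:0.5} + 1/3 * {A:0.25, C:0.75}
  p3 <- build_combined_fraction(c(A = 2, B = 2), c(A = 1, C = 3), c(2, 1))
  expect_equal(p3$rel[["A"]], 2 / 3 * 0.5 + 1 / 3 * 0.25)
  expect_equal(p3$rel[["B"]], 1 / 3)
  expect_equal(p3$rel[["C"]], 0.25)
})

test_that("the two-fraction sweep matches hand arithmetic on small mixtures", {
  # r = 50: mix of {A:.6, B:.4} and {A:.2, C:.8} is {A:.4, B:.2, C:.4};
  # everything clears 0.01% at depth 10,000 -> richness 3
  small <- pooled_profile(c(A = 0.6, B = 0.4))
  large <- pooled_profile(c(A = 0.2, C = 0.8))
  curve <- two_fraction_sweep(small, large)
  expect_identical(curve$richness[curve$x == 50], 3L)
  # endpoints collapse to the thresholded constituent profiles
  expect_identical(curve$richness[curve$x == 100], 2L)
  expect_identical(curve$richness[curve$x == 0], 2L)
})

test_that("the sweep equals the brute-force oracle exactly across all 21 ratios", {
  set.seed(404)
  for (i in 1:12) {
    n1 <- sample(2:10, 1); n2 <- sample(2:10, 1)
    # mix abundant and near-threshold OTUs, with partial overlap
    small <- rel <- runif(n1, 1e-5, 1)
    names(small) <- sample(LETTERS[1:12], n1)
    small <- small / sum(small)
    large <- runif(n2, 1e-5, 1)
    names(large) <- sample(LETTERS[1:12], n2)
    large <- large / sum(large)
    curve <- two_fraction_sweep(pooled_profile(small), pooled_profile(large))
    expect_identical(curve$richness,
                     as.integer(brute_force_sweep(small, large)))
  }
})

test_that("exclusive rare OTUs in the large fraction push the optimum off the endpoint", {
  # the large composite holds rare exclusives at 0.03%: present at r < 100,
  # absent from the pure small profile, so an intermediate ratio wins
  small <- c(A = 0.7, B = 0.2999, C = 0.0001)
  large <- c(D = 0.9991, E = 0.0003, F = 0.0003, G = 0.0003)
  curve <- two_fraction_sweep(pooled_profile(small), pooled_profile(large))
  best <- curve$x[which.max(curve$richness)]
  expect_gt(best, 0)
  expect_lt(best, 100)
  # and the brute-force oracle agrees over the whole sweep
  expect_identical(curve$richness, as.integer(brute_force_sweep(small, large)))
})

test_that("pooled profiles always sum to one when any OTU is present", {
  set.seed(505)
  for (i in 1:10) {
    tabs <- list(S = c(A = rpois(1, 50) + 1, B = rpois(1, 5)),
                 M = c(B = rpois(1, 20), C = rpois(1, 9) + 1),
                 L = c(D = rpois(1, 100) + 1),
                 XL = c(E = rpois(1, 3) + 1))
    w <- runif(4, 0.01, 5)
    p <- pool_by_weight(tabs, setNames(w, c("S", "M", "L", "XL")))
    expect_equal(sum(p$rel), 1, tolerance = 1e-12)
  }
})

test_that("the equal quarter-depth pool unions per-fraction survivors at 0.04%", {
  # four disjoint fractions, 10 OTUs each, all abundant: union of 40
  tabs <- lapply(setNames(0:3, c("S", "M", "L", "XL")), function(k) {
    setNames(rep(100, 10), paste0("OTU_", k * 10 + 1:10))
  })
  expect_identical(as.integer(equal_quarter_pool(tabs)), 40L)

  # identical fractions: union is one fraction's surviving count
  same <- setNames(rep(list(c(A = 60, B = 40)), 4), c("S", "M", "L", "XL"))
  expect_identical(as.integer(equal_quarter_pool(same)), 2L)

  # an OTU at 0.03% in every fraction is excluded everywhere
  with_rare <- setNames(rep(list(c(A = 99970, B = 30)), 4), c("S", "M", "L", "XL"))
  q <- equal_quarter_pool(with_rare)
  expect_identical(as.integer(q), 1L)
  expect_false("B" %in% attr(q, "otus"))

  expect_error(equal_quarter_pool(with_rare[1:3]), "missing fraction.*XL")
})
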