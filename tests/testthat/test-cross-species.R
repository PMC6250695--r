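# Independent oracle: hypergeometric tail by direct summation of
# binomial-coefficient table probabilities over all tables with the
# observed margins.
oracle_fisher_greater <- function(a, b, c, d) {
  n <- a + b + c + d; m <- a + b; k <- a + c
  amax <- min(m, k)
  p <- 0
  for (j in a:amax) {
    p <- p + exp(lchoose(m, j) + lchoose(n - m, k - j) - lchoose(n, k))
  }
  p
}

test_that("ortholog mapping applies its resolution policy and reports drops", {
  map <- ortholog_map(c("m1", "m2"), c("h1", "h2"))
  out <- apply_ortholog_map(c("m1", "m3"), map)
  expect_identical(out$mapped, "h1")
  expect_identical(out$n_dropped, 1L)
  expect_identical(out$dropped_ids, "m3")

  # one source with two targets is dropped entirely under one2one_only
  multi <- ortholog_map(c("m1", "m1", "m2"), c("h1", "h1b", "h2"),
                        policy = "one2one_only")
  expect_identical(apply_ortholog_map(c("m1", "m2"), multi)$mapped, "h2")

  # ... but resolved alphabetically under first_alphabetical
  alpha <- ortholog_map(c("m1", "m1", "m2"), c("h1b", "h1", "h2"),
                        policy = "first_alphabetical")
  expect_setequal(apply_ortholog_map(c("m1", "m2"), alpha)$mapped, c("h1", "h2"))

  expect_identical(apply_ortholog_map(character(0), map)$mapped, character(0))
  # reverse direction
  expect_identical(apply_ortholog_map("h2", map, "target_to_source")$mapped, "m2")
})

test_that("fisher_overlap matches the hand-enumerated worked example", {
  universe <- sprintf("u%d", 1:8)
  l1 <- universe[1:4]              # a = 3, b = 1
  l2 <- c(universe[1:3], universe[5])  # c = 1, d = 3
  res <- fisher_overlap(l1, l2, universe, "greater")
  expect_identical(c(res$a, res$b, res$c, res$d), c(3L, 1L, 1L, 3L))
  expect_equal(res$p_value, 17 / 70, tolerance = 1e-12)
  expect_identical(round(res$p_value, 5), 0.24286)
  expect_equal(res$p_value, oracle_fisher_greater(3, 1, 1, 3), tolerance = 1e-12)
  expect_equal(res$odds_ratio, 9)

  # depleted overlap: Haldane-corrected OR, p(greater) >= 0.5
  res0 <- fisher_overlap(universe[1:2], universe[3:4], universe, "greater")
  expect_identical(res0$a, 0L)
  expect_equal(res0$odds_ratio, (0.5 * 4.5) / (2.5 * 2.5))
  expect_gte(res0$p_value, 0.5)

  # degenerate: both lists equal the universe
  resU <- fisher_overlap(universe, universe, universe, "greater")
  expect_identical(resU$a, 8L)
  expect_equal(resU$p_value, 1)

  expect_error(fisher_overlap(c("u1", "alien"), l2, universe),
               "alien", class = "revsig_validation_error")
})

test_that("fisher_overlap agrees with stats::fisher.test p-values", {
  set.seed(40)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    universe <- sprintf("u%d", seq_len(n))
    l1 <- sample(universe, sample(2:(n - 2), 1))
    l2 <- sample(universe, sample(2:(n - 2), 1))
    res_g <- fisher_overlap(l1, l2, universe, "greater")
    res_t <- fisher_overlap(l1, l2, universe, "two_sided")
    tab <- matrix(c(res_g$a, res_g$b, res_g$c, res_g$d), 2, byrow = TRUE)
    expect_equal(res_g$p_value, fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
    expect_equal(res_t$p_value, fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("overlap tables always partition the universe and are symmetric", {
  set.seed(41)
  for (i in 1:15) {
    n <- sample(20:100, 1)
    universe <- sprintf("u%d", seq_len(n))
    l1 <- sample(universe, sample(1:n, 1))
    l2 <- sample(universe, sample(1:n, 1))
    r12 <- fisher_overlap(l1, l2, universe)
    r21 <- fisher_overlap(l2, l1, universe)
    expect_identical(r12$a + r12$b + r12$c + r12$d, n)
    expect_equal(r12$p_value, r21$p_value)
    expect_equal(r12$odds_ratio, r21$odds_ratio)
  }
})

test_that("enlarging the universe with unlisted genes cannot weaken enrichment", {
  set.seed(42)
  for (i in 1:10) {
    universe <- sprintf("u%d", 1:50)
    l1 <- sample(universe, 15)
    l2 <- sample(universe, 15)
    p_small <- fisher_overlap(l1, l2, universe)$p_value
    bigger <- c(universe, sprintf("extra%d", 1:30))
    p_big <- fisher_overlap(l1, l2, bigger)$p_value
    expect_lte(p_big, p_small + 1e-12)
  }
})

test_that("concordance and reversal tests work end-to-end on mapped inputs", {
  # perfect concordance: identical lists on a 100-gene universe
  universe <- sprintf("h%03d", 1:100)
  sig <- directional_signature(universe[1:20], universe[21:40], n_per_arm = 20)
  mset <- structure(list(up = universe[1:20], down = universe[21:40], tau = 0.5),
                    class = "ThresholdSet")
  cc <- concordance_test(sig, mset, universe)
  expect_identical(cc$up$a, 20L)
  expect_lt(cc$up$p_value, 1e-15)

  # disjoint lists covering the universe
  mset2 <- structure(list(up = universe[41:100], down = character(0), tau = 0.5),
                     class = "ThresholdSet")
  cc2 <- concordance_test(sig, mset2, universe)
  expect_identical(cc2$up$a, 0L)

  expect_error(concordance_test(sig, mset, character(0)),
               class = "revsig_validation_error")
  expect_error(reversal_test(character(0), mset, universe),
               class = "revsig_validation_error")

  # an implanted-reversal synthetic pair yields strong enrichment
  cfg <- sim_config(seed = 50, reversal_fraction = 0.7, concordance = 0.8)
  px <- run_xspecies_pair(cfg)
  rev <- reversal_test(px$sig$up, threshold_set(px$de_trt, 0.5), px$universe,
                       px$map)
  expect_lt(rev$p_value, 0.05)
  expect_gt(rev$odds_ratio, 1)
})
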