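# Brute-force oracle: evaluate the full running sum D(k) over every
# rank position and return the deviation of maximum magnitude.
oracle_es <- function(member_ids, z) {
  ord <- names(z)[order(-z, names(z))]
  hit <- ord %in% member_ids
  t <- sum(hit); n <- length(z)
  d <- c(0, cumsum(ifelse(hit, 1 / t, -1 / (n - t))))
  dmax <- max(d); dmin <- min(d)
  # an exact tie of the extreme deviations carries no direction
  if (abs(dmax + dmin) < 1e-9) 0 else if (dmax > -dmin) dmax else dmin
}

oracle_score <- function(z, sig) {
  eu <- oracle_es(sig$up, z)
  ed <- oracle_es(sig$down, z)
  if (sign(eu) != sign(ed) && eu != 0 && ed != 0) (eu - ed) / 2 else 0
}

test_that("ks score equals the brute-force running sum on a 10-feature toy", {
  z <- stats::setNames(c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1), letters[1:10])
  # up tags occupy the top 2 ranks, down tags the bottom 3
  sig <- directional_signature(c("a", "b"), c("h", "i", "j"), n_per_arm = 3)
  expect_equal(ks_connectivity(z, sig), oracle_score(z, sig))
  expect_equal(ks_connectivity(z, sig), 1)  # maximal for this geometry

  # random geometries against the oracle
  set.seed(20)
  for (i in 1:25) {
    ps <- make_profile_sig(i, n_features = 40, n_up = sample(2:6, 1),
                           n_down = sample(2:6, 1))
    expect_equal(ks_connectivity(ps$z, ps$sig), oracle_score(ps$z, ps$sig),
                 tolerance = 1e-12)
  }
})

test_that("ks score is bounded, antisymmetric and rank-invariant", {
  set.seed(21)
  for (i in 1:20) {
    ps <- make_profile_sig(100 + i, n_features = 120, n_up = 10, n_down = 10)
    s <- ks_connectivity(ps$z, ps$sig)
    expect_true(abs(s) <= 1)
    # negating all z negates the score
    expect_equal(ks_connectivity(-ps$z, ps$sig), -s, tolerance = 1e-12)
    # swapping the arms negates the score
    swapped <- directional_signature(ps$sig$down, ps$sig$up,
                                     n_per_arm = ps$sig$n_per_arm)
    expect_equal(ks_connectivity(ps$z, swapped), -s, tolerance = 1e-12)
    # strictly monotone transform of z leaves the score unchanged
    expect_equal(ks_connectivity(tanh(ps$z / 3) * 5 + 2, ps$sig), s,
                 tolerance = 1e-12)
  }
})

test_that("ks scoring validates its inputs", {
  ps <- make_profile_sig(1, n_features = 30, n_up = 4, n_down = 4)
  bad <- directional_signature(c(ps$sig$up, "missing_feature"), ps$sig$down,
                               n_per_arm = 5)
  expect_error(ks_connectivity(ps$z, bad), "missing_feature",
               class = "revsig_validation_error")
  empty <- directional_signature(character(0), ps$sig$down, n_per_arm = 4)
  expect_error(ks_connectivity(ps$z, empty), class = "revsig_validation_error")
})

test_that("permutation p is reproducible and detects an implanted inverse compound", {
  cfg <- sim_config(seed = 30, inverse_strength = 2)
  ps <- make_profile_sig(30, n_features = 978, n_up = 50, n_down = 50)
  cpd <- simulate_compound_collection(cfg, ps$sig)
  hit <- cpd$truth$compound_id[cpd$truth$is_inverse_hit]
  z <- stats::setNames(cpd$profiles$values[, hit], cpd$profiles$gene_ids)
  res <- permutation_p(z, ps$sig, n_perms = 999, seed = 2, compound_id = hit)
  expect_lt(res$p_perm, 0.01)
  expect_lt(res$score, 0)
  expect_identical(res$direction_call, "inverse")
  res2 <- permutation_p(z, ps$sig, n_perms = 999, seed = 2, compound_id = hit)
  expect_identical(res2$p_perm, res$p_perm)
  expect_error(permutation_p(z, ps$sig, n_perms = 50),
               class = "revsig_validation_error")
})

test_that("screen ranks the implanted compound first and makes no calls at alpha 0", {
  cfg <- sim_config(seed = 31)
  ps <- make_profile_sig(31, n_features = 978, n_up = 50, n_down = 50)
  cpd <- simulate_compound_collection(cfg, ps$sig)
  hit <- cpd$truth$compound_id[cpd$truth$is_inverse_hit]
  screen <- screen_collection(cpd$profiles, ps$sig, alpha = 0.05,
                              n_perms = 499, seed = 31)
  expect_identical(screen$compound_id[1], hit)
  expect_identical(screen$direction_call[1], "inverse")
  expect_true(all(diff(screen$score) >= 0))

  none <- screen_collection(cpd$profiles, ps$sig, alpha = 0, n_perms = 199,
                            seed = 31)
  expect_true(all(none$direction_call == "null"))

  empty <- expression_matrix(
    matrix(numeric(0), nrow = 978, ncol = 0,
           dimnames = list(landmark_ids(978), character(0))), "zscore")
  expect_identical(nrow(screen_collection(empty, ps$sig, n_perms = 199)), 0L)
})

test_that("spearman sensitivity scorer opposes the signature for the inverse hit", {
  cfg <- sim_config(seed = 32, inverse_strength = 2)
  ps <- make_profile_sig(32, n_features = 978, n_up = 50, n_down = 50)
  cpd <- simulate_compound_collection(cfg, ps$sig)
  hit <- cpd$truth$compound_id[cpd$truth$is_inverse_hit]
  z <- stats::setNames(cpd$profiles$values[, hit], cpd$profiles$gene_ids)
  expect_lt(ks_connectivity(z, ps$sig, method = "spearman"), -0.5)
  expect_true(abs(ks_connectivity(ps$z, ps$sig, method = "spearman")) <= 1)
})
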