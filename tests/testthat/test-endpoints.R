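# Independent brute-force oracle for the exact rank-sum p: enumerate
# every same-size subset of the pooled values via bitmasks.
oracle_ranksum <- function(a, b) {
  pooled <- c(a, b); n <- length(pooled); nA <- length(a)
  r <- rank(pooled)
  obs <- sum(r[seq_len(nA)])
  ws <- numeric(0)
  for (mask in 0:(2^n - 1)) {
    bits <- which(intToBits(mask)[1:n] == as.raw(1))
    if (length(bits) == nA) ws <- c(ws, sum(r[bits]))
  }
  mu <- mean(ws)
  mean(abs(ws - mu) >= abs(obs - mu) - 1e-9)
}

test_that("NAS rubric maps histology to component scores", {
  r <- nas_score(steatosis_pct = 70, foci_per_field = 5,
                 ballooning_category = "many")
  expect_identical(r$steatosis_score, 3L)
  expect_identical(r$inflammation_score, 3L)
  expect_identical(r$ballooning_score, 2L)
  expect_identical(r$total, 8L)

  # band edges: 5 and 33 open the next band, 66 stays in band 2
  steat <- function(p) nas_score(steatosis_pct = p, foci_per_field = 0,
                                 ballooning_category = "none")$steatosis_score
  expect_identical(sapply(c(0, 4.9, 5, 32.9, 33, 66, 66.1), steat),
                   c(0L, 0L, 1L, 1L, 2L, 2L, 3L))
  foci <- function(f) nas_score(steatosis_pct = 0, foci_per_field = f,
                                ballooning_category = "none")$inflammation_score
  expect_identical(sapply(c(0, 0.5, 1.9, 2, 4, 4.5), foci),
                   c(0L, 1L, 1L, 2L, 2L, 3L))

  expect_error(nas_score(steatosis_pct = 130, foci_per_field = 0,
                         ballooning_category = "none"),
               class = "revsig_validation_error")
  expect_error(nas_score(steatosis_pct = 10, foci_per_field = -1,
                         ballooning_category = "none"),
               class = "revsig_validation_error")
})

test_that("NAS totals equal the component sum on random records", {
  set.seed(70)
  hist <- data.frame(steatosis_pct = runif(50, 0, 100),
                     foci_per_field = rpois(50, 2),
                     ballooning_category = sample(c("none", "few", "many"), 50,
                                                  replace = TRUE))
  scored <- nas_score_table(hist)
  expect_identical(scored$nas_total,
                   scored$steatosis_score + scored$inflammation_score +
                     scored$ballooning_score)
  expect_true(all(scored$nas_total >= 0 & scored$nas_total <= 8))
})

test_that("exact rank-sum p matches enumeration oracles (with and without ties)", {
  # the most extreme split of 4 values
  r <- wilcoxon_ranksum(c(1, 2), c(3, 4))
  expect_equal(r$p_two_sided, 2 / 6)
  # identical multisets give p = 1
  expect_equal(wilcoxon_ranksum(c(3, 1, 2), c(2, 1, 3))$p_two_sided, 1)
  expect_equal(wilcoxon_ranksum(rep(5, 3), rep(5, 4))$p_two_sided, 1)

  set.seed(71)
  for (i in 1:30) {
    nA <- sample(2:5, 1); nB <- sample(2:5, 1)
    a <- if (i %% 2) rnorm(nA) else sample(1:4, nA, replace = TRUE)  # ties half the time
    b <- if (i %% 2) rnorm(nB) else sample(1:4, nB, replace = TRUE)
    expect_equal(wilcoxon_ranksum(a, b, mode = "exact")$p_two_sided,
                 oracle_ranksum(a, b), tolerance = 1e-12)
  }

  # tie-free exact p agrees with the standard distribution-based test
  for (i in 1:10) {
    a <- rnorm(4); b <- rnorm(5)
    expect_equal(wilcoxon_ranksum(a, b, mode = "exact")$p_two_sided,
                 wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-9)
  }
})

test_that("normal approximation tracks the exact mode at moderate n", {
  set.seed(72)
  for (i in 1:5) {
    a <- rnorm(6); b <- rnorm(6, mean = i / 4)
    pe <- wilcoxon_ranksum(a, b, mode = "exact")$p_two_sided
    pn <- wilcoxon_ranksum(a, b, mode = "normal")$p_two_sided
    expect_lt(abs(pe - pn), 0.02)
  }
  expect_error(wilcoxon_ranksum(numeric(0), 1:3), class = "revsig_validation_error")
})

test_that("anova_lsd matches hand-computed sums of squares and the t-test identity", {
  res <- anova_lsd(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(6, 7, 8)))
  # SSB = 42, SSW = 6 with df 2 and 6: F = 21
  expect_equal(res$F, 21, tolerance = 1e-6)
  expect_equal(res$p_anova, pf(21, 2, 6, lower.tail = FALSE), tolerance = 1e-9)
  expect_identical(nrow(res$pairwise), 3L)

  # two groups: F = t^2 of the pooled-variance t-test
  set.seed(73)
  a <- rnorm(8); b <- rnorm(7, 0.5)
  res2 <- anova_lsd(list(a = a, b = b))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(res2$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(res2$p_anova, tt$p.value, tolerance = 1e-9)
  expect_equal(res2$pairwise$p, tt$p.value, tolerance = 1e-9)

  # all values identical: F = 0 and every p = 1
  res3 <- anova_lsd(list(a = c(5, 5), b = c(5, 5), c = c(5, 5)))
  expect_identical(res3$F, 0)
  expect_identical(res3$p_anova, 1)
  expect_true(all(res3$pairwise$p == 1))

  expect_error(anova_lsd(list(a = 1, b = c(1, 2))), class = "revsig_validation_error")
})

test_that("ddct follows the comparative-Ct arithmetic", {
  ct <- data.frame(
    sample_id = rep(c("c1", "c2", "t1", "t2"), each = 2),
    group = rep(c("control", "control", "treated", "treated"), each = 2),
    gene = rep(c("Ifng", "Rplp0"), 4),
    ct = c(25, 20, 25, 20, 27, 20, 27, 20))
  res <- ddct(ct, "Ifng", "Rplp0", "control", "treated")
  expect_equal(res$ddct, 2)
  expect_equal(res$fold_change, 0.25)
  expect_equal(res$delta_ct$delta_ct, rep(c(5, 7), each = 2))

  # ddCt = 0 <=> fold change 1; reciprocal identity
  ct0 <- ct; ct0$ct[ct0$gene == "Ifng"] <- 25
  expect_equal(ddct(ct0, "Ifng", "Rplp0", "control", "treated")$fold_change, 1)
  flipped <- ddct(ct, "Ifng", "Rplp0", "treated", "control")
  expect_equal(res$fold_change * flipped$fold_change, 1)

  # missing reference Ct names the sample
  bad <- ct[!(ct$sample_id == "t1" & ct$gene == "Rplp0"), ]
  expect_error(ddct(bad, "Ifng", "Rplp0", "control", "treated"), "t1",
               class = "revsig_validation_error")
})

test_that("outlier mask is single-pass mean +/- 2 SD", {
  v <- c(1:9, 100)
  mask <- outlier_mask(v)
  expect_identical(which(!mask), 10L)  # mean 14.5, SD ~30.15: only 100 is out

  expect_true(all(outlier_mask(rep(3, 5))))
  expect_error(outlier_mask(c(1, 2)), class = "revsig_validation_error")

  # single pass: after removing one extreme the rule is NOT re-applied,
  # so a second, milder outlier survives
  v2 <- c(rep(10, 10), 25, 1000)
  mask2 <- outlier_mask(v2)
  expect_identical(which(!mask2), 12L)
  expect_true(mask2[11])
})
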