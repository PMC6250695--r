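mk_status_tables <- function() {
  dis <- make_de(c("up_rev", "up_norev", "dn_rev", "not_deg"),
                 log2fc = c(2, 2, -2, 1.5),
                 p = c(0.001, 0.001, 0.001, 0.5),
                 p_adj = c(0.004, 0.004, 0.004, 0.5))
  trt <- make_de(c("up_rev", "up_norev", "dn_rev", "not_deg"),
                 log2fc = c(-1, 0.3, 1.2, -2),
                 p = c(0.001, 0.9, 0.001, 0.001),
                 p_adj = c(0.004, 0.9, 0.004, 0.004))
  list(dis = dis, trt = trt)
}

test_that("reversal classification follows the sign-opposition rule with FDR gates", {
  tabs <- mk_status_tables()
  st <- classify_reversal(tabs$dis, tabs$trt, alpha = 0.05)
  expect_identical(st$status[st$gene_id == "up_rev"], "deg_reversed")
  expect_identical(st$status[st$gene_id == "up_norev"], "deg_not_reversed")
  expect_identical(st$status[st$gene_id == "dn_rev"], "deg_reversed")
  # non-DEG stays non-DEG no matter what treatment does
  expect_identical(st$status[st$gene_id == "not_deg"], "not_deg")

  # swapping the sign convention of both contrasts leaves status unchanged
  flip <- function(tab) { tab$log2fc <- -tab$log2fc; tab }
  st2 <- classify_reversal(flip(tabs$dis), flip(tabs$trt), alpha = 0.05)
  expect_identical(st$status, st2$status)

  # genes present in one table only are excluded with a warning
  extra <- make_de(c(tabs$dis$gene_id, "lonely"), c(tabs$dis$log2fc, 1),
                   p = c(tabs$dis$p, 0.01), p_adj = c(tabs$dis$p_adj, 0.04))
  expect_warning(st3 <- classify_reversal(extra, tabs$trt), "excluded")
  expect_identical(attr(st3, "n_excluded"), 1L)
})

test_that("the strict variant additionally requires approach to healthy", {
  dis <- make_de(c("overshoot", "partial"), c(2, 2),
                 p = c(0.001, 0.001), p_adj = c(0.002, 0.002))
  trt <- make_de(c("overshoot", "partial"), c(-5, -1),
                 p = c(0.001, 0.001), p_adj = c(0.002, 0.002))
  st_sign <- classify_reversal(dis, trt, rule = "sign")
  st_strict <- classify_reversal(dis, trt, rule = "strict")
  expect_true(all(st_sign$is_reversed))
  # overshooting past healthy by more than the disease shift fails strict
  expect_false(st_strict$is_reversed[st_strict$gene_id == "overshoot"])
  expect_true(st_strict$is_reversed[st_strict$gene_id == "partial"])
})

test_that("pathway percent reversed does the arithmetic and keeps empty pathways", {
  tabs <- mk_status_tables()
  st <- classify_reversal(tabs$dis, tabs$trt)
  gsc <- gene_set_collection(list(
    all = c("up_rev", "up_norev", "dn_rev", "not_deg"),
    just_rev = c("up_rev", "dn_rev", "not_deg"),
    no_degs = "not_deg",
    padded = c("up_rev", "dn_rev", sprintf("unmeasured%d", 1:7))))
  pw <- pathway_percent_reversed(st, gsc)
  expect_equal(pw$percent_reversed[pw$pathway_name == "all"], 100 * 2 / 3)
  expect_equal(pw$percent_reversed[pw$pathway_name == "just_rev"], 100)
  expect_true(is.na(pw$percent_reversed[pw$pathway_name == "no_degs"]))
  expect_identical(pw$n_disease_degs[pw$pathway_name == "no_degs"], 0L)
  # invariant to pathway members that are not disease DEGs / not measured
  expect_equal(pw$percent_reversed[pw$pathway_name == "padded"], 100)
})

test_that("reversal rate is monotone in treatment strength and ~50% ungated at null", {
  rates <- sapply(c(0.02, 0.1, 0.25), function(rho) {
    cfg <- sim_config(seed = 60, samples_per_group = 6,
                      reversal_fraction = 1, reversal_strength = rho)
    m <- simulate_three_group_counts(cfg)
    dis <- de_test(m$counts, m$design, "healthy", "disease")
    trt <- de_test(m$counts, m$design, "disease", "treated")
    st <- classify_reversal(dis, trt, treated_alpha = 1)  # ungated sign rule
    pw <- pathway_percent_reversed(
      st, gene_set_collection(list(all = m$counts$gene_ids)))
    pw$percent_reversed
  })
  expect_true(all(diff(rates) > 0))
  # at rho ~ 0 the ungated sign rule is a coin flip on noise
  expect_lt(abs(rates[1] - 50), 12)
  expect_gt(rates[3], 90)
})

test_that("marker matrix is relative to the reference group", {
  set.seed(61)
  x <- matrix(rnbinom(40 * 6, mu = 100, size = 50) + 1, 40, 6)
  em <- make_counts(x)
  des <- sample_design(em$sample_ids, rep(c("healthy", "disease", "treated"), 2),
                       c("healthy", "disease", "treated"))
  rel <- marker_relative_matrix(em, des, c("g01", "g02", "g03"), "healthy",
                                size_factors = structure(rep(1, 6), class = "SizeFactors",
                                                         names = em$sample_ids))
  expect_true(all(rel[, "healthy"] == 0))

  # a group whose mean (plus pseudocount) doubles the reference scores +1
  y <- matrix(c(9, 9, 19, 19), 1, 4, dimnames = list("m", sprintf("s%d", 1:4)))
  emy <- expression_matrix(y, "counts")
  desy <- sample_design(colnames(y), c("ref", "ref", "hi", "hi"), c("ref", "hi"))
  rely <- marker_relative_matrix(emy, desy, "m", "ref",
                                 size_factors = structure(rep(1, 4), class = "SizeFactors",
                                                          names = colnames(y)))
  expect_equal(unname(rely["m", "hi"]), 1)

  expect_warning(
    rel2 <- marker_relative_matrix(em, des, c("g01", "absent_marker"), "healthy",
                                   size_factors = structure(rep(1, 6), class = "SizeFactors",
                                                            names = em$sample_ids)),
    "absent_marker")
  expect_identical(rownames(rel2), "g01")
})
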