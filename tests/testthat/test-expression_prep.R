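test_that("discrimination scores follow (PM - MM) / (PM + MM)", {
  expect_equal(discrimination_scores(100, 100), 0)
  expect_equal(discrimination_scores(100, 0), 1)
  expect_equal(discrimination_scores(c(200, 150), c(100, 50)), c(1 / 3, 1 / 2))
  expect_warning(r <- discrimination_scores(c(0, 100), c(0, 50)), "excluded")
  expect_equal(r, 1 / 3)
  expect_error(suppressWarnings(discrimination_scores(0, 0)), "zero total")
  expect_error(discrimination_scores(c(1, 2), 1), "equal length")
})

test_that("detection call reproduces the exact signed-rank tail", {
  # all 11 scores above tau: only the all-positive sign assignment reaches
  # the observed rank sum, p = 2^-11
  dc <- detection_call(rep(0.5, 11), tau = 0.015)
  expect_equal(dc$p_value, 2^-11, tolerance = 1e-12)
  expect_equal(dc$call, "present")
  # same p bracketed between tighter alphas gives a marginal call
  dc2 <- detection_call(rep(0.5, 11), tau = 0.015,
                        alpha1 = 1e-4, alpha2 = 1e-3)
  expect_equal(dc2$call, "marginal")
  # symmetry around tau carries no evidence
  dc3 <- detection_call(c(-0.3, 0.3, -0.2, 0.2), tau = 0)
  expect_gte(dc3$p_value, 0.5)
  expect_equal(dc3$call, "absent")
  expect_warning(dc4 <- detection_call(rep(0.015, 5), tau = 0.015), "degenerate")
  expect_equal(dc4$p_value, 1)
})

test_that("detection p-value matches exhaustive enumeration and is permutation invariant", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(3:12, 1)
    R <- round(stats::runif(n, -1, 1), 1)  # rounding forces frequent ties
    tau <- sample(c(0, 0.015, 0.1), 1)
    p_pkg <- detection_call(R, tau)$p_value
    expect_equal(p_pkg, oracle_signed_rank_p(R, tau), tolerance = 1e-12,
                 info = paste("case", i))
    expect_equal(detection_call(sample(R), tau)$p_value, p_pkg)
  }
})

test_that("signed fold change has magnitude >= 1 and is antisymmetric", {
  expect_equal(signed_fold_change(100, 50), 2)
  expect_equal(signed_fold_change(50, 100), -2)
  expect_equal(signed_fold_change(100, 100), 1)
  expect_error(signed_fold_change(0, 10), "strictly positive")
  set.seed(1)
  a <- stats::runif(50, 1, 500)
  b <- stats::runif(50, 1, 500)
  fc <- signed_fold_change(a, b)
  expect_true(all(abs(fc) >= 1))
  uneq <- a != b
  expect_equal(signed_fold_change(b, a)[uneq], -fc[uneq])
})

test_that("changed-gene selection applies the 2-fold and presence rules", {
  path <- withr::local_tempfile(fileext = ".tsv")
  gm <- write_toy_expression(path, rows = list(
    STRONG = c(250, 250, 250, 100, 100, 100, 100, 100, 100),  # 2.5x ipsi
    WEAK   = c(190, 190, 190, 100, 100, 100, 100, 100, 100),  # 1.9x ipsi
    GHOST  = c(300, 300, 300, 300, 300, 300, 100, 100, 100))) # 3x both sides
  ex <- read_expression_tsv(path, gm)
  # GHOST is absent in one sample on each injured side
  calls <- expand.grid(gene = c("STRONG", "WEAK", "GHOST"),
                       sample = names(gm), stringsAsFactors = FALSE)
  calls$call <- "present"
  calls$call[calls$gene == "GHOST" & calls$sample %in% c("I1", "C1")] <- "absent"
  de <- select_changed_genes(ex, calls)
  expect_equal(de$gene[de$side == "ipsilateral"], "STRONG")
  expect_equal(de$signed_fc[de$side == "ipsilateral"], 2.5)
  expect_false("WEAK" %in% de$gene)
  expect_false("GHOST" %in% de$gene)
  # exactly 2-fold counts as changed
  gm2 <- write_toy_expression(path, rows = list(
    EDGE = c(200, 200, 200, 100, 100, 100, 100, 100, 100)))
  expect_true("EDGE" %in% select_changed_genes(read_expression_tsv(path, gm2))$gene)
})

test_that("raising the fold-change cutoff never adds genes", {
  p <- sim_params(n_genes = 300, seed = 11)
  sim <- simulate_expression(p)
  sets <- lapply(c(2, 3, 5), function(cut) {
    de <- select_changed_genes(sim$expr, sim$calls,
                               analysis_config(fold_change_cutoff = cut))
    paste(de$gene, de$side)
  })
  expect_true(all(sets[[2]] %in% sets[[1]]))
  expect_true(all(sets[[3]] %in% sets[[2]]))
})

test_that("missing naive group is a configuration error", {
  vals <- matrix(1:4, 2, 2, dimnames = list(c("A", "B"), c("s1", "s2")))
  ex <- expression_matrix(vals, c(s1 = "ipsilateral", s2 = "contralateral"))
  expect_error(select_changed_genes(ex), "missing group: naive")
})

test_that("probe-level table produces one call per gene and sample", {
  pp_present <- simulate_probe_pairs(11, present = TRUE, seed = 2)
  pp_absent <- simulate_probe_pairs(11, present = FALSE, seed = 3)
  probes <- rbind(
    data.frame(gene = "on", sample = "I1", pp_present),
    data.frame(gene = "off", sample = "I1", pp_absent))
  calls <- detection_call_table(probes)
  expect_equal(nrow(calls), 2)
  expect_equal(calls$call[calls$gene == "ON"], "present")
  expect_gt(calls$p_value[calls$gene == "OFF"],
            calls$p_value[calls$gene == "ON"])
})
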