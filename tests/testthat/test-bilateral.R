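test_that("linearization maps signed fold changes onto the ratio scale", {
  expect_equal(linearize(2), 2)
  expect_equal(linearize(-4), 0.25)
  expect_equal(linearize(1), 1)
  expect_error(linearize(0.5), "below 1")
})

test_that("the generalized ratio reproduces published values", {
  pairs <- rbind(
    c(37.905, 2.370, 15.994),    # both up, ipsi larger
    c(-11.813, -23.824, 2.017),  # both down, contra more extreme
    c(-4.426, -2.032, -2.178),   # both down, ipsi more extreme
    c(3.088, -9.429, 29.117),    # up ipsi, down contra
    c(-4.383, 5.614, -24.606))   # down ipsi, up contra
  got <- bilateral_ratio(pairs[, 1], pairs[, 2])
  expect_equal(got, pairs[, 3], tolerance = 0.0005 / max(abs(pairs[, 3])))
  expect_true(all(abs(got - pairs[, 3]) <= 0.0005))
  expect_equal(bilateral_ratio(2, 2), 1)
})

test_that("the generalized rule equals each piecewise case formula on its domain", {
  set.seed(7)
  rand_fc <- function(n, up) {
    m <- exp(stats::runif(n, log(2), log(40)))
    if (up) m else -m
  }
  domains <- list(
    function() { a <- sort(rand_fc(2, TRUE), decreasing = TRUE); a },      # both up, ipsi larger
    function() { a <- sort(rand_fc(2, FALSE), decreasing = TRUE); a },     # both down, contra more extreme
    function() { a <- sort(rand_fc(2, FALSE)); a },                        # both down, ipsi more extreme
    function() c(rand_fc(1, TRUE), rand_fc(1, FALSE)),                     # up / down
    function() c(rand_fc(1, FALSE), rand_fc(1, TRUE)))                     # down / up
  for (d in domains) {
    for (rep in 1:40) {
      fc <- d()
      if (fc[1] == fc[2]) next
      expect_equal(bilateral_ratio(fc[1], fc[2]), piecewise_ratio(fc[1], fc[2]),
                   tolerance = 1e-12)
    }
  }
})

test_that("the ratio is antisymmetric under side exchange", {
  set.seed(3)
  for (i in 1:100) {
    fc <- sample(c(-1, 1), 2, replace = TRUE) * exp(stats::runif(2, log(1), log(40)))
    r <- bilateral_ratio(fc[1], fc[2])
    if (abs(abs(r) - 1) < 1e-9) next
    expect_equal(bilateral_ratio(fc[2], fc[1]), -r, tolerance = 1e-12)
  }
})

test_that("classification distinguishes unique, similar and different changes", {
  expect_equal(classify_gene(2.5, NA), "unique_ipsi")
  expect_equal(classify_gene(NA, -3), "unique_contra")
  expect_equal(classify_gene(15.558, 2.399), "common_different")  # ratio 6.485
  expect_equal(classify_gene(2.4, 2.2), "common_similar")         # ratio ~1.09
  expect_equal(classify_gene(4, 2), "common_similar")             # exactly 2 stays similar
  expect_error(classify_gene(NA, NA), "neither side")
})

test_that("raising the ratio cutoff never moves genes from similar to different", {
  set.seed(5)
  fc_i <- sample(c(-1, 1), 80, TRUE) * exp(stats::runif(80, log(2), log(40)))
  fc_c <- sample(c(-1, 1), 80, TRUE) * exp(stats::runif(80, log(2), log(40)))
  lo <- classify_gene(fc_i, fc_c, ratio_cutoff = 2)
  hi <- classify_gene(fc_i, fc_c, ratio_cutoff = 4)
  expect_true(all(hi[lo == "common_similar"] == "common_similar"))
})

test_that("bilateral table and partition summary count cells and directions", {
  de <- data.frame(
    gene = c("A", "B", "C", "D", "D"),
    side = c("ipsilateral", "ipsilateral", "contralateral",
             "ipsilateral", "contralateral"),
    signed_fc = c(3, 2.5, -2.2, 2.4, 2.2))
  bt <- bilateral_table(de)
  expect_equal(nrow(bt), 4)
  expect_equal(bt$partition[bt$gene == "D"], "common_similar")
  expect_true(is.na(bt$ratio[bt$gene == "A"]))
  s <- partition_summary(bt)
  expect_equal(unname(s$counts),  c(2, 1, 1, 0))
  expect_equal(s$unique_ipsi$pct_up, 100L)
  expect_equal(s$unique_contra$pct_down, 100L)
  expect_equal(s$total, 4)

  empty <- partition_summary(bilateral_table(de[0, ]))
  expect_equal(empty$total, 0)
  expect_true(all(empty$counts == 0))
})

test_that("the sixth configuration (both up, contra larger) is flagged extrapolated", {
  de <- data.frame(gene = c("X", "X"), side = c("ipsilateral", "contralateral"),
                   signed_fc = c(2.1, 9))
  bt <- bilateral_table(de)
  expect_true(bt$extrapolated)
  expect_lt(bt$ratio, 0)
  expect_equal(bt$partition, "common_different")
})

test_that("bilateral TSV output rounds to reporting precision", {
  de <- data.frame(gene = c("A", "A"), side = c("ipsilateral", "contralateral"),
                   signed_fc = c(37.90481, 2.37003))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_bilateral_tsv(bilateral_table(de), path)
  out <- utils::read.delim(path)
  expect_equal(out$fc_i, 37.905)
  expect_equal(out$ratio, round(bilateral_ratio(37.90481, 2.37003), 3))
})
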