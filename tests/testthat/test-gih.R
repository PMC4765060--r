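test_that("induced subnetwork keeps only GOI-GOI edges and labels components", {
  inter <- data.frame(from = c("A", "A"), to = c("B", "X"))
  net <- induce_subnetwork(c("A", "B", "C"), inter)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$main_component, c("A", "B"))
  expect_equal(connection_count("C", net), 0)

  # no induced edges at all: everyone isolated, no main component
  net0 <- induce_subnetwork(c("A", "B"), data.frame(from = "X", to = "Y"))
  expect_length(net0$main_component, 0)

  # equal-size components: tie broken by smallest member
  net2 <- induce_subnetwork(c("A", "B", "C", "D"),
                            data.frame(from = c("C", "A"), to = c("D", "B")))
  expect_equal(net2$main_component, c("A", "B"))
  expect_error(induce_subnetwork(character(0), inter), "empty GOI")
})

test_that("connection counts are distinct first-order neighbours", {
  star <- data.frame(from = rep("HUB", 3), to = c("L1", "L2", "L3"))
  net <- induce_subnetwork(c("HUB", "L1", "L2", "L3"), star)
  expect_equal(connection_count("HUB", net), 3)
  tri <- data.frame(from = c("A", "B", "C"), to = c("B", "C", "A"))
  nett <- induce_subnetwork(c("A", "B", "C"), tri)
  expect_equal(connection_count("A", nett), 2)
  # duplicated and antiparallel edges count once; self-loops are dropped
  messy <- data.frame(from = c("A", "B", "A", "A"), to = c("B", "A", "B", "A"))
  netm <- suppressWarnings(induce_subnetwork(c("A", "B"), messy))
  expect_equal(connection_count("A", netm), 1)
  selfy <- suppressWarnings(induce_subnetwork(c("S", "T"),
                                              data.frame(from = "S", to = "S")))
  expect_equal(connection_count("S", selfy), 0)
  expect_error(connection_count("NOPE", net), "not in network")
})

test_that("connection counts match brute-force enumeration on random graphs", {
  set.seed(13)
  for (i in 1:15) {
    n <- sample(5:50, 1)
    edges <- random_edges(n, p = 0.15)
    nodes <- sprintf("N%02d", seq_len(n))
    net <- induce_subnetwork(nodes, edges)
    for (g in sample(nodes, min(8, n))) {
      expect_equal(connection_count(g, net), oracle_neighbour_count(g, edges))
    }
  }
})

test_that("tier thresholds reproduce both published operationalizations", {
  t145 <- tier_thresholds(145)
  expect_equal(t145$primary_gt, 14L)    # 10% of 144 = 14.4, round half up
  expect_equal(t145$secondary_min, 8L)  # 5% of 144 = 7.2, ceiling
  t78 <- tier_thresholds(78)
  expect_equal(t78$primary_gt, 8L)      # 10% of 77 = 7.7
  expect_equal(t78$secondary_min, 4L)   # 5% of 77 = 3.85
  t21 <- tier_thresholds(21)
  expect_equal(t21$primary_gt, 2L)
  expect_equal(t21$secondary_min, 1L)
  expect_error(tier_thresholds(1), "at least 2")
})

test_that("hierarchy tiers partition the GOI and follow the thresholds", {
  star <- data.frame(from = rep("AHUB", 9), to = sprintf("L%d", 1:9))
  goi <- c("AHUB", sprintf("L%d", 1:9), sprintf("ISO%d", 1:5))
  h <- build_hierarchy(goi, star)
  thr <- attr(h, "thresholds")
  expect_equal(thr$n_main, 10)
  expect_equal(h$tier[h$gene == "AHUB"], "primary")   # 9 > 1
  expect_true(all(h$tier[grepl("^L", h$gene)] == "secondary"))  # 1 >= 1
  expect_true(all(h$tier[grepl("^ISO", h$gene)] == "orphan"))
  expect_equal(nrow(h), length(goi))
  expect_equal(sum(table(h$tier)), length(goi))
  # orphan <=> zero connections
  expect_identical(h$tier == "orphan", h$connections == 0L)

  h0 <- build_hierarchy(c("A", "B"), data.frame(from = "X", to = "Y"))
  expect_true(all(h0$tier == "orphan"))
})

test_that("off-main-component genes are tiered but flagged", {
  edges <- data.frame(from = c("A", "A", "A", "P"), to = c("B", "C", "D", "Q"))
  h <- build_hierarchy(c("A", "B", "C", "D", "P", "Q"), edges)
  expect_true(all(h$off_main_component[h$gene %in% c("P", "Q")]))
  expect_false(any(h$off_main_component[h$gene %in% c("A", "B")]))
})

test_that("adding an edge never lowers a tier at fixed component size", {
  set.seed(21)
  nodes <- sprintf("N%02d", 1:20)
  # connected base graph: a path plus random chords
  base <- data.frame(from = nodes[-20], to = nodes[-1])
  extra <- random_edges(20, 0.1)
  edges <- unique(rbind(base, extra))
  h1 <- build_hierarchy(nodes, edges)
  ord <- c(primary = 1, secondary = 2, peripheral = 3, orphan = 4)
  # add a chord between two existing main-component nodes
  pick <- setdiff(t(combn(nodes, 2)) |> apply(1, paste, collapse = " "),
                  paste(edges$from, edges$to))
  add <- strsplit(sample(pick, 1), " ")[[1]]
  h2 <- build_hierarchy(nodes, rbind(edges, data.frame(from = add[1], to = add[2])))
  r1 <- stats::setNames(ord[h1$tier], h1$gene)
  r2 <- stats::setNames(ord[h2$tier], h2$gene)
  expect_true(all(r2[names(r1)] <= r1))
})

test_that("planted hubs are recovered into the primary tier", {
  p <- sim_params(seed = 5)
  goi <- sprintf("GOI%03d", 1:120)
  net <- simulate_network(p, goi)
  h <- build_hierarchy(goi, net$edges)
  expect_equal(sort(h$gene[h$tier == "primary" & h$gene %in% net$hubs]),
               net$hubs)
  thr <- attr(h, "thresholds")
  for (hub in net$hubs) {
    expect_gt(h$connections[h$gene == hub], thr$primary_gt)
  }
})
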