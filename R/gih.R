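#' Induce the GOI interaction subnetwork
#'
#' Restricts an interaction edge list to the genes of interest: the
#' network's nodes are the GOI (including isolated ones) and its edges are
#' the interaction pairs with both endpoints among the GOI. Connected
#' components are labelled; the main component is the largest, with ties
#' broken in favour of the component containing the lexicographically
#' smallest gene symbol.
#'
#' @param goi Character vector of GOI symbols (non-empty) or a
#'   `"bigih_goi"` object.
#' @param interactions Edge list data frame (`from`, `to`), e.g. from
#'   [read_edge_list()].
#' @return List of class `"bigih_goinet"` with elements `nodes`, `edges`,
#'   `graph` (igraph), `component` (named integer vector) and
#'   `main_component` (character vector; empty when the network has no
#'   edges).
#' @export
induce_subnetwork <- function(goi, interactions) {
  if (inherits(goi, "bigih_goi")) goi <- goi$genes
  goi <- unique(normalize_symbol(goi))
  if (length(goi) == 0) stop("empty GOI set")
  edges <- edge_list(interactions$from, interactions$to)
  keep <- edges$from %in% goi & edges$to %in% goi
  edges <- edges[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = goi))
  comp <- igraph::components(g)
  membership <- comp$membership[goi]
  main <- character(0)
  nonsingleton <- which(comp$csize >= 2)
  if (length(nonsingleton)) {
    sizes <- comp$csize[nonsingleton]
    best <- nonsingleton[sizes == max(sizes)]
    if (length(best) > 1) {
      # tie: component holding the smallest symbol
      firsts <- vapply(best, function(b) min(goi[membership == b]), character(1))
      best <- best[order(firsts)][1]
    }
    main <- sort(goi[membership == best])
  }
  structure(list(nodes = goi, edges = edges, graph = g,
                 component = membership, main_component = main),
            class = "bigih_goinet")
}

#' Number of direct interaction partners within the GOI network
#'
#' Distinct first-order neighbours of a gene among the GOI, excluding the
#' gene itself; duplicated or antiparallel input edges count once.
#'
#' @param gene Gene symbol.
#' @param net A `"bigih_goinet"` object.
#' @return Integer neighbour count.
#' @export
connection_count <- function(gene, net) {
  gene <- normalize_symbol(gene)
  if (!gene %in% net$nodes) stop("gene not in network: ", gene)
  length(igraph::neighbors(net$graph, gene))
}

#' Tier thresholds from the main-component size
#'
#' Hierarchy tiers are defined by first-order connection counts relative to
#' the number of *other* genes in the main network component (`n_main - 1`):
#' primary requires strictly more than `primary_fraction` of them
#' (threshold integerized by rounding half up), secondary requires at least
#' `secondary_fraction` of them (integerized by ceiling). For a main
#' component of 145 genes this gives primary > 14 and secondary >= 8
#' connections; for 78 genes, primary > 8 and secondary >= 4.
#'
#' @param n_main Size of the main component (>= 2).
#' @param primary_fraction,secondary_fraction Tier fractions.
#' @return List with `n_main`, `primary_gt` (primary requires connections
#'   strictly greater) and `secondary_min` (secondary requires at least).
#' @export
tier_thresholds <- function(n_main, primary_fraction = 0.10,
                            secondary_fraction = 0.05) {
  if (n_main < 2) stop("main component must have at least 2 genes")
  round_half_up <- function(x) floor(x + 0.5)
  primary_gt <- round_half_up(primary_fraction * (n_main - 1))
  # tiny main components can invert the integerized cutoffs; clamp so the
  # secondary band stays well defined (possibly empty)
  secondary_min <- min(ceiling(secondary_fraction * (n_main - 1)), primary_gt)
  list(n_main = n_main, primary_gt = as.integer(primary_gt),
       secondary_min = as.integer(secondary_min))
}

#' Build the gene interaction hierarchy
#'
#' Counts each GOI's direct interaction partners among the GOI and assigns
#' tiers from thresholds computed on the main-component size: primary
#' (connections > `primary_gt`), secondary (`secondary_min` to
#' `primary_gt`), peripheral (at least one connection but fewer than
#' `secondary_min`) and orphan (no connections). Connected genes outside
#' the main component are tiered by the same thresholds and flagged
#' `off_main_component`. When the induced network has no edges at all,
#' every gene is an orphan.
#'
#' @param goi Character vector of GOI or a `"bigih_goi"` object.
#' @param interactions Edge list data frame (`from`, `to`).
#' @param config An [analysis_config()] supplying the tier fractions.
#' @param fc Optional named numeric vector of signed fold changes carried
#'   through for reporting.
#' @return Data frame with columns `gene`, `connections`, `tier`,
#'   `off_main_component` (and `signed_fc` when `fc` is given), sorted by
#'   tier, then descending connections, then symbol. The thresholds are
#'   attached as attribute `"thresholds"`.
#' @export
build_hierarchy <- function(goi, interactions, config = analysis_config(),
                            fc = NULL) {
  net <- induce_subnetwork(goi, interactions)
  deg <- igraph::degree(net$graph)
  deg <- deg[net$nodes]
  n_main <- length(net$main_component)
  if (all(deg == 0)) {
    thr <- NULL
    tier <- rep("orphan", length(deg))
  } else {
    thr <- tier_thresholds(n_main, config$tier_primary_fraction,
                           config$tier_secondary_fraction)
    tier <- ifelse(deg == 0, "orphan",
            ifelse(deg > thr$primary_gt, "primary",
            ifelse(deg >= thr$secondary_min, "secondary", "peripheral")))
  }
  out <- data.frame(gene = net$nodes,
                    connections = as.integer(deg),
                    tier = tier,
                    off_main_component = deg > 0 &
                      !(net$nodes %in% net$main_component),
                    stringsAsFactors = FALSE)
  if (!is.null(fc)) {
    names(fc) <- normalize_symbol(names(fc))
    out$signed_fc <- unname(fc[out$gene])
  }
  tier_rank <- match(out$tier, c("primary", "secondary", "peripheral", "orphan"))
  out <- out[order(tier_rank, -out$connections, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "thresholds") <- thr
  out
}
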