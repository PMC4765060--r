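# Independent brute-force oracles, deliberately written with different
# machinery than the package implementations they check.

# One-sided signed-rank p for H1: median(x) > tau, by exhaustive
# enumeration of sign assignments (midranks for tied absolute deviations).
oracle_signed_rank_p <- function(x, tau) {
  d <- x - tau
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  w_all <- apply(signs, 1, function(s) sum(r[s]))
  mean(w_all >= w_obs - 1e-9)
}

# Hypergeometric upper tail by direct summation of binomial coefficients.
oracle_fisher_tail <- function(k, n, K, N) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Distinct-neighbour count by scanning the raw edge rows.
oracle_neighbour_count <- function(gene, edges) {
  nb <- c(edges$to[edges$from == gene], edges$from[edges$to == gene])
  length(unique(setdiff(nb, gene)))
}

# Random undirected simple graph over n named nodes.
random_edges <- function(n, p = 0.1) {
  nodes <- sprintf("N%02d", seq_len(n))
  pairs <- t(combn(nodes, 2))
  keep <- stats::runif(nrow(pairs)) < p
  data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
             stringsAsFactors = FALSE)
}

# The five published piecewise case formulas for the bilateral ratio,
# transcribed literally, each valid only on its own domain.
piecewise_ratio <- function(fc_i, fc_c) {
  if (fc_i > 0 && fc_c > 0 && fc_i > fc_c) return(fc_i / fc_c)          # both up, ipsi larger
  if (fc_i < 0 && fc_c < 0 && fc_i > fc_c) return(1 / (fc_i / fc_c))    # both down, contra more extreme
  if (fc_i < 0 && fc_c < 0 && fc_i < fc_c) return(-1 / (fc_c / fc_i))   # both down, ipsi more extreme
  if (fc_i > 0 && fc_c < 0) return(fc_i / -(1 / fc_c))                  # up ipsi, down contra
  if (fc_i < 0 && fc_c > 0) return(fc_c / (1 / fc_i))                   # down ipsi, up contra
  stop("pair outside the five published domains")
}

# Tiny 3-gene x 9-sample expression fixture written to a temp TSV.
write_toy_expression <- function(path,
                                 rows = list(GENE1 = c(250, 250, 250, 100, 100, 100, 100, 100, 100))) {
  samples <- c(paste0("I", 1:3), paste0("C", 1:3), paste0("N", 1:3))
  lines <- c(paste(c("gene", samples), collapse = "\t"),
             vapply(names(rows), function(g) {
               paste(c(g, rows[[g]]), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  stats::setNames(rep(c("ipsilateral", "contralateral", "naive"), each = 3),
                  samples)
}
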