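#' Simulation parameters
#'
#' Defaults emulate the bilateral injury study design the pipeline targets:
#' three groups (ipsilateral, contralateral, naive) of three replicates;
#' about 45% of genes differentially expressed, split 40% unique-ipsilateral
#' / 15% unique-contralateral / 45% common; 18% of the common genes changed
#' differently between sides; 88% of unique-ipsilateral changes up-regulated
#' and 75% of unique-contralateral changes down-regulated; fold-change
#' magnitudes log-uniform on `[2, 40]`.
#'
#' @param n_genes Number of genes.
#' @param replicates Replicates per group.
#' @param fraction_de Fraction of genes differentially expressed on at
#'   least one side.
#' @param p_unique_ipsi,p_unique_contra Fractions of DE genes changing on
#'   one side only (the remainder change on both sides).
#' @param p_different Fraction of common (both-side) DE genes that change
#'   differently (bilateral ratio magnitude above `ratio_cutoff`).
#' @param p_up_unique_ipsi Probability a unique-ipsilateral change is up.
#' @param p_down_unique_contra Probability a unique-contralateral change is
#'   down.
#' @param p_up_common_similar Probability a similarly-changing common gene
#'   moves up (on both sides).
#' @param p_negative_ratio Probability a changed-differently gene is more
#'   extreme contralaterally (negative bilateral ratio).
#' @param fc_range Range of fold-change magnitudes (log-uniform).
#' @param ratio_cutoff Ratio cutoff the generator plants classes against.
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline intensities.
#' @param noise_sigma Log-scale standard deviation of multiplicative
#'   replicate noise (0 = noiseless).
#' @param dropout Probability an expressed gene receives a non-present
#'   detection call in one injured-side sample.
#' @param pa_m Edges added per vertex in the preferential-attachment
#'   network model (0 = empty network).
#' @param n_background Non-GOI genes included in the simulated network.
#' @param n_hubs Number of planted hub genes among the GOI.
#' @param hub_degree_factor Planted hubs receive edges within the GOI until
#'   their induced degree reaches this multiple of the primary-tier cutoff.
#' @param n_sets Number of annotation sets (one focal + background).
#' @param set_size Genes per annotation set.
#' @param hub_enrichment Fraction of the planted hubs forced into the focal
#'   annotation set (0 = no signal).
#' @param seed Root seed; sub-generators derive their own streams from it.
#' @return List of class `"bigih_sim_params"`.
#' @export
sim_params <- function(n_genes = 2000,
                       replicates = 3,
                       fraction_de = 0.45,
                       p_unique_ipsi = 0.40,
                       p_unique_contra = 0.15,
                       p_different = 0.18,
                       p_up_unique_ipsi = 0.88,
                       p_down_unique_contra = 0.75,
                       p_up_common_similar = 0.73,
                       p_negative_ratio = 3 / 73,
                       fc_range = c(2, 40),
                       ratio_cutoff = 2,
                       baseline_meanlog = log(500),
                       baseline_sdlog = 1,
                       noise_sigma = 0.15,
                       dropout = 0,
                       pa_m = 2,
                       n_background = 50,
                       n_hubs = 3,
                       hub_degree_factor = 2,
                       n_sets = 10,
                       set_size = 25,
                       hub_enrichment = 1,
                       seed = 1) {
  p <- as.list(environment())
  probs <- c(p$fraction_de, p$p_unique_ipsi, p$p_unique_contra,
             p$p_different, p$p_up_unique_ipsi, p$p_down_unique_contra,
             p$p_up_common_similar, p$p_negative_ratio, p$dropout,
             p$hub_enrichment)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (p$p_unique_ipsi + p$p_unique_contra > 1) {
    stop("unique-side fractions exceed 1")
  }
  if (p$fc_range[1] < 2 || p$fc_range[2] <= p$fc_range[1]) {
    stop("fc_range must be increasing with lower bound >= 2")
  }
  if (p$n_genes < 1 || p$replicates < 1) stop("counts must be positive")
  structure(p, class = "bigih_sim_params")
}

rlunif <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

#' Simulate a bilateral expression experiment
#'
#' Draws a planted ground truth (partition class, directions and true fold
#' changes per gene), log-normal naive baselines, group means scaled by the
#' true fold changes, multiplicative log-normal replicate noise, and a
#' detection-call table. Deterministic given the seed.
#'
#' @param params A [sim_params()] object.
#' @param seed Seed for this stage (defaults to the root seed).
#' @return List with `expr` (a `"bigih_expr"`), `calls` (detection-call
#'   data frame) and `truth` (data frame: `gene`, `class`, `fc_i`, `fc_c`).
#' @export
simulate_expression <- function(params = sim_params(), seed = params$seed) {
  set.seed(seed)
  n <- params$n_genes
  genes <- sprintf("G%05d", seq_len(n))
  n_de <- round(n * params$fraction_de)
  n_ui <- round(n_de * params$p_unique_ipsi)
  n_uc <- round(n_de * params$p_unique_contra)
  n_common <- n_de - n_ui - n_uc
  n_diff <- round(n_common * params$p_different)
  n_sim <- n_common - n_diff
  de_idx <- sample(n, n_de)
  cls <- rep("none", n)
  cls[de_idx] <- rep(c("unique_ipsi", "unique_contra", "common_similar",
                       "common_different"),
                     times = c(n_ui, n_uc, n_sim, n_diff))
  lo <- params$fc_range[1]; hi <- params$fc_range[2]
  rc <- params$ratio_cutoff
  fc_i <- rep(NA_real_, n)
  fc_c <- rep(NA_real_, n)
  sgn <- function(up) ifelse(up, 1, -1)

  ui <- which(cls == "unique_ipsi")
  fc_i[ui] <- sgn(stats::runif(length(ui)) < params$p_up_unique_ipsi) *
    rlunif(length(ui), lo, hi)
  uc <- which(cls == "unique_contra")
  fc_c[uc] <- sgn(stats::runif(length(uc)) >= params$p_down_unique_contra) *
    rlunif(length(uc), lo, hi)

  cs <- which(cls == "common_similar")
  if (length(cs)) {
    s <- sgn(stats::runif(length(cs)) < params$p_up_common_similar)
    base <- rlunif(length(cs), lo, hi / rc)
    r <- stats::runif(length(cs), 1, 0.95 * rc)  # keep clear of the cutoff
    ipsi_larger <- stats::runif(length(cs)) < 0.5
    fc_i[cs] <- s * ifelse(ipsi_larger, base * r, base)
    fc_c[cs] <- s * ifelse(ipsi_larger, base, base * r)
  }

  cd <- which(cls == "common_different")
  if (length(cd)) {
    m <- length(cd)
    r <- rlunif(m, 1.1 * rc, 10 * rc)  # planted |ratio|, clear of the cutoff
    pattern <- sample(c("both_up", "opposite", "both_down"), m, replace = TRUE)
    neg <- stats::runif(m) < params$p_negative_ratio
    u <- rlunif(m, lo, hi / r)
    lin_small <- ifelse(pattern == "both_up", u,
                 ifelse(pattern == "both_down", 1 / (r * u),
                        1 / rlunif(m, lo, hi)))
    lin_big <- ifelse(pattern == "both_up", u * r,
               ifelse(pattern == "both_down", 1 / u,
                      rlunif(m, lo, hi)))
    to_fc <- function(lin) ifelse(lin >= 1, lin, -1 / lin)
    fc_i[cd] <- to_fc(ifelse(neg, lin_small, lin_big))
    fc_c[cd] <- to_fc(ifelse(neg, lin_big, lin_small))
  }

  truth <- data.frame(gene = genes, class = cls, fc_i = fc_i, fc_c = fc_c,
                      stringsAsFactors = FALSE)

  naive_mean <- stats::rlnorm(n, params$baseline_meanlog, params$baseline_sdlog)
  lin_or_1 <- function(fc) ifelse(is.na(fc), 1, linearize(fc))
  means <- cbind(ipsilateral = naive_mean * lin_or_1(fc_i),
                 contralateral = naive_mean * lin_or_1(fc_c),
                 naive = naive_mean)
  reps <- params$replicates
  groups <- rep(c("ipsilateral", "contralateral", "naive"), each = reps)
  samples <- paste0(rep(c("IPSI", "CONTRA", "NAIVE"), each = reps),
                    "_", rep(seq_len(reps), 3))
  vals <- matrix(0, n, length(samples), dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    noise <- if (params$noise_sigma > 0) {
      exp(stats::rnorm(n, 0, params$noise_sigma))
    } else 1
    vals[, j] <- means[, groups[j]] * noise
  }
  expr <- expression_matrix(vals, stats::setNames(groups, samples))

  calls <- expand.grid(gene = genes, sample = samples,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  calls$call <- "present"
  calls$p_value <- 0.01
  if (params$dropout > 0) {
    injured <- calls$sample %in% samples[groups != "naive"]
    drop <- injured & stats::runif(nrow(calls)) < params$dropout
    calls$call[drop] <- "absent"
    calls$p_value[drop] <- 0.5
  }
  list(expr = expr, calls = calls, truth = truth)
}

#' Simulate a gene interaction network with planted hubs
#'
#' Generates a preferential-attachment graph over the GOI plus background
#' genes, then adds edges from each planted hub to other GOI until the
#' hub's induced (within-GOI) degree reaches `hub_degree_factor` times the
#' primary-tier cutoff computed for a main component spanning all GOI, so
#' planted hubs land in the primary tier with high probability.
#' Deterministic given the seed.
#'
#' @param params A [sim_params()] object.
#' @param goi Character vector of GOI symbols.
#' @param seed Seed for this stage (defaults to root seed + 1).
#' @return List with `edges` (deduplicated edge-list data frame) and
#'   `hubs` (character vector of planted hub genes).
#' @export
simulate_network <- function(params = sim_params(), goi,
                             seed = params$seed + 1) {
  set.seed(seed)
  goi <- unique(normalize_symbol(goi))
  if (params$n_hubs > length(goi)) {
    stop("more planted hubs requested than GOI available")
  }
  nodes <- c(goi, if (params$n_background > 0)
    sprintf("BG%04d", seq_len(params$n_background)))
  hubs <- if (params$n_hubs > 0) sort(sample(goi, params$n_hubs)) else character(0)
  if (params$pa_m < 1) {
    base <- data.frame(from = character(), to = character(),
                       stringsAsFactors = FALSE)
  } else {
    g <- igraph::sample_pa(length(nodes), power = 1, m = params$pa_m,
                           directed = FALSE)
    igraph::V(g)$name <- sample(nodes)
    base <- igraph::as_data_frame(g, what = "edges")
  }
  from <- base$from; to <- base$to
  if (length(hubs)) {
    primary_gt <- floor(0.10 * (length(goi) - 1) + 0.5)
    target <- ceiling(params$hub_degree_factor * max(primary_gt, 1))
    for (h in hubs) {
      nb <- unique(c(to[from == h], from[to == h]))
      nb <- intersect(nb, goi)
      need <- target - length(nb)
      if (need > 0) {
        cand <- setdiff(goi, c(h, nb))
        add <- sample(cand, min(need, length(cand)))
        from <- c(from, rep(h, length(add)))
        to <- c(to, add)
      }
    }
  }
  edges <- if (length(from)) {
    suppressWarnings(edge_list(from, to))
  } else {
    data.frame(from = character(), to = character(), stringsAsFactors = FALSE)
  }
  list(edges = edges, hubs = hubs)
}

#' Simulate annotation sets
#'
#' One focal set enriched for the planted hubs (`hub_enrichment` controls
#' how many hubs are forced in; 0 gives a purely random set, i.e. no
#' signal) plus random background sets, all drawn from the given universe.
#'
#' @param params A [sim_params()] object.
#' @param hubs Character vector of planted hub genes.
#' @param universe Character vector of genes to draw members from.
#' @param seed Seed for this stage (defaults to root seed + 2).
#' @return Named list of character vectors (GMT-writable); the focal set is
#'   named `"focal"`.
#' @export
simulate_annotations <- function(params = sim_params(), hubs, universe,
                                 seed = params$seed + 2) {
  set.seed(seed)
  universe <- unique(normalize_symbol(universe))
  hubs <- intersect(unique(normalize_symbol(hubs)), universe)
  size <- min(params$set_size, length(universe))
  n_forced <- round(params$hub_enrichment * min(length(hubs), size))
  forced <- if (n_forced > 0) sample(hubs, n_forced) else character(0)
  fill <- sample(setdiff(universe, forced), size - length(forced))
  sets <- list(focal = sort(c(forced, fill)))
  for (i in seq_len(max(params$n_sets - 1, 0))) {
    sets[[sprintf("background_%02d", i)]] <- sort(sample(universe, size))
  }
  attr(sets, "description") <- stats::setNames(
    c("hub-enriched focal set", rep("random background set",
                                    length(sets) - 1)), names(sets))
  sets
}

#' Simulate probe-pair intensities for one gene and sample
#'
#' Opt-in probe-level generator for exercising the detection-call stage:
#' present targets get perfect-match intensities well above mismatch,
#' absent targets get exchangeable PM/MM noise.
#'
#' @param n_pairs Number of probe pairs (11 is typical).
#' @param present Logical: simulate a present target?
#' @param seed Seed.
#' @return Data frame with columns `pm`, `mm`.
#' @export
simulate_probe_pairs <- function(n_pairs = 11, present = TRUE, seed = 1) {
  set.seed(seed)
  mm <- stats::rlnorm(n_pairs, log(100), 0.3)
  pm <- if (present) mm * stats::rlnorm(n_pairs, log(3), 0.3)
        else stats::rlnorm(n_pairs, log(100), 0.3)
  data.frame(pm = pm, mm = mm)
}
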