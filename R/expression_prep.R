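#' Probe-pair discrimination scores
#'
#' For each perfect-match/mismatch probe pair the discrimination score
#' `R = (PM - MM) / (PM + MM)` measures the pair's ability to detect its
#' target; it lies in `[-1, 1]`. Pairs with `PM + MM == 0` carry no signal
#' and are excluded with a warning.
#'
#' @param pm,mm Non-negative numeric vectors of equal length: perfect-match
#'   and mismatch intensities.
#' @return Numeric vector of scores for the scored pairs.
#' @export
discrimination_scores <- function(pm, mm) {
  if (length(pm) != length(mm) || length(pm) < 1) {
    stop("pm and mm must have equal length >= 1")
  }
  if (any(pm < 0) || any(mm < 0)) stop("intensities must be non-negative")
  tot <- pm + mm
  zero <- tot == 0
  if (any(zero)) {
    warning(sum(zero), " probe pair(s) with PM + MM = 0 excluded")
  }
  if (all(zero)) stop("all probe pairs have zero total intensity")
  (pm[!zero] - mm[!zero]) / tot[!zero]
}

# Exact one-sided signed-rank p-value for H1: median(x) > tau.
# Zeros (x == tau) are discarded; midranks handle tied |deviations|.
# Exact by enumeration of sign assignments up to n = 16 (psignrank when the
# absolute deviations are tie-free), normal approximation with tie
# correction beyond.
signed_rank_p <- function(x, tau) {
  d <- x - tau
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0
  if (!ties && n <= 50) {
    # P(W+ >= w) under the null
    return(stats::psignrank(w - 1, n, lower.tail = FALSE))
  }
  if (n <= 16) {
    # enumerate all 2^n sign assignments of the midranks
    total <- 0L
    npat <- 2L^n
    for (pat in 0:(npat - 1L)) {
      signs <- bitwAnd(bitwShiftR(pat, 0:(n - 1L)), 1L) == 1L
      if (sum(r[signs]) >= w - 1e-9) total <- total + 1L
    }
    return(total / npat)
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  stats::pnorm((w - mu - 0.5) / sqrt(sigma2), lower.tail = FALSE)
}

#' Detection call from discrimination scores
#'
#' One-sided exact Wilcoxon signed-rank test of H1: `median(R) > tau`. The
#' resulting detection p-value maps deterministically to a call: present if
#' `p < alpha1`, marginal if `alpha1 <= p < alpha2`, absent otherwise. The
#' call is invariant under permutation of the probe pairs.
#'
#' @param R Numeric vector of discrimination scores (non-empty).
#' @param tau Score threshold (default 0.015).
#' @param alpha1,alpha2 Call cutoffs, `0 < alpha1 < alpha2 < 1`.
#' @return List with elements `p_value` and `call`
#'   (`"present"`, `"marginal"` or `"absent"`).
#' @export
detection_call <- function(R, tau = 0.015, alpha1 = 0.04, alpha2 = 0.06) {
  if (length(R) < 1) stop("R must be non-empty")
  if (!(alpha1 > 0 && alpha1 < alpha2 && alpha2 < 1)) {
    stop("need 0 < alpha1 < alpha2 < 1")
  }
  if (all(R == tau)) {
    warning("all discrimination scores equal tau; degenerate absent call")
    return(list(p_value = 1, call = "absent"))
  }
  p <- signed_rank_p(R, tau)
  call <- if (p < alpha1) "present" else if (p < alpha2) "marginal" else "absent"
  list(p_value = p, call = call)
}

#' Detection calls for a probe-level table
#'
#' @param probes Data frame with columns `gene`, `sample`, `pm`, `mm`
#'   (one row per probe pair).
#' @param config An [analysis_config()] supplying `tau`, `alpha1`, `alpha2`.
#' @return Data frame with columns `gene`, `sample`, `call`, `p_value`.
#' @export
detection_call_table <- function(probes, config = analysis_config()) {
  need <- c("gene", "sample", "pm", "mm")
  if (!all(need %in% names(probes))) {
    stop("probes needs columns: ", paste(need, collapse = ", "))
  }
  probes$gene <- normalize_symbol(probes$gene)
  key <- interaction(probes$gene, probes$sample, drop = TRUE)
  out <- lapply(split(probes, key), function(g) {
    R <- discrimination_scores(g$pm, g$mm)
    dc <- detection_call(R, config$tau, config$alpha1, config$alpha2)
    data.frame(gene = g$gene[1], sample = g$sample[1],
               call = dc$call, p_value = dc$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Signed fold change of two positive means
#'
#' Returns `mean_exp / mean_ctrl` when the ratio is at least 1 and the
#' negated reciprocal `-(mean_ctrl / mean_exp)` otherwise, so the magnitude
#' is always at least 1 and the sign gives the direction of change.
#'
#' @param mean_exp,mean_ctrl Strictly positive group means (vectorized).
#' @return Numeric vector of signed fold changes.
#' @export
signed_fold_change <- function(mean_exp, mean_ctrl) {
  if (any(mean_exp <= 0) || any(mean_ctrl <= 0)) {
    stop("group means must be strictly positive")
  }
  r <- mean_exp / mean_ctrl
  ifelse(r >= 1, r, -1 / r)
}

#' Select changed genes per side
#'
#' Computes, for each gene, the signed fold change of the ipsilateral and
#' contralateral group means against the naive group mean, and retains a
#' gene for a side when `|signed_fc| >= fold_change_cutoff` and the
#' presence rule holds. Under the default rule a gene passes the presence
#' gate (for both sides) when it is called present in every ipsilateral
#' sample or in every contralateral sample; only the strict `"present"`
#' call counts.
#'
#' @param expr A `"bigih_expr"` expression matrix with all three groups.
#' @param calls Optional data frame of detection calls with columns `gene`,
#'   `sample`, `call`. When `NULL` every gene passes the presence gate.
#' @param config An [analysis_config()].
#' @return Data frame with columns `gene`, `side` (`"ipsilateral"` or
#'   `"contralateral"`), `signed_fc`, `present_ok`, one row per retained
#'   gene-side record.
#' @export
select_changed_genes <- function(expr, calls = NULL,
                                 config = analysis_config()) {
  stopifnot(inherits(expr, "bigih_expr"))
  groups <- expr$groups
  for (g in c("ipsilateral", "contralateral", "naive")) {
    if (!any(groups == g)) stop("missing group: ", g)
  }
  vals <- expr$values
  gmean <- function(g) rowMeans(vals[, groups == g, drop = FALSE])
  m_naive <- gmean("naive")
  if (any(m_naive <= 0)) stop("non-positive naive mean; cannot form fold changes")
  present_all <- function(side) {
    samp <- colnames(vals)[groups == side]
    if (is.null(calls)) {
      return(stats::setNames(rep(TRUE, nrow(vals)), rownames(vals)))
    }
    calls$gene <- normalize_symbol(calls$gene)
    ok <- rep(TRUE, nrow(vals))
    names(ok) <- rownames(vals)
    for (s in samp) {
      cs <- calls[calls$sample == s, ]
      status <- stats::setNames(cs$call, cs$gene)[rownames(vals)]
      ok <- ok & !is.na(status) & status == "present"
    }
    ok
  }
  p_ipsi <- present_all("ipsilateral")
  p_contra <- present_all("contralateral")
  gate <- switch(config$presence_rule,
                 either_side_all = list(ipsilateral = p_ipsi | p_contra,
                                        contralateral = p_ipsi | p_contra),
                 per_side_all = list(ipsilateral = p_ipsi,
                                     contralateral = p_contra))
  out <- lapply(c("ipsilateral", "contralateral"), function(side) {
    fc <- signed_fold_change(gmean(side), m_naive)
    keep <- abs(fc) >= config$fold_change_cutoff & gate[[side]]
    data.frame(gene = rownames(vals)[keep], side = rep(side, sum(keep)),
               signed_fc = unname(fc[keep]),
               present_ok = unname(gate[[side]][keep]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
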