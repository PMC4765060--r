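#' Relative expression by the delta-delta-Ct method
#'
#' For each record, `dCt = Ct(target) - Ct(reference)`. The naive
#' calibrator `dCt2` is the mean naive `dCt`; each experimental replicate's
#' `ddCt = dCt - dCt2` yields a relative expression of `2^-ddCt` under the
#' perfect-doubling efficiency assumption. Replicates are compared against
#' the naive mean (not paired), and per-group mean and standard error are
#' reported.
#'
#' @param ct Data frame with columns `sample`, `group` (`ipsilateral`,
#'   `contralateral` or `naive`), `target`, `ct_target`, `ct_reference`.
#' @param target Gene symbol to quantify (required when `ct` holds several
#'   targets).
#' @return List of class `"bigih_ddct"` with `target`, `dct2` (naive mean
#'   dCt), `replicates` (data frame: `sample`, `group`, `ddct`,
#'   `rel_expr`) and `summary` (data frame: `group`, `n`, `mean`, `se`).
#' @export
delta_delta_ct <- function(ct, target = NULL) {
  need <- c("sample", "group", "target", "ct_target", "ct_reference")
  if (!all(need %in% names(ct))) {
    stop("ct needs columns: ", paste(need, collapse = ", "))
  }
  ct$target <- normalize_symbol(ct$target)
  targets <- unique(ct$target)
  if (is.null(target)) {
    if (length(targets) > 1) stop("several targets present; specify one")
    target <- targets
  } else {
    target <- normalize_symbol(target)
  }
  ct <- ct[ct$target == target, , drop = FALSE]
  if (!nrow(ct)) stop("no Ct records for target ", target)
  if (!any(ct$group == "naive")) stop("missing naive Ct records")
  if (any(!is.finite(ct$ct_target)) || any(!is.finite(ct$ct_reference))) {
    stop("Ct values must be finite")
  }
  dct <- ct$ct_target - ct$ct_reference
  dct2 <- mean(dct[ct$group == "naive"])
  ddct <- dct - dct2
  reps <- data.frame(sample = ct$sample, group = ct$group,
                     ddct = ddct, rel_expr = 2^(-ddct),
                     stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(split(reps, reps$group), function(g) {
    data.frame(group = g$group[1], n = nrow(g), mean = mean(g$rel_expr),
               se = if (nrow(g) > 1) stats::sd(g$rel_expr) / sqrt(nrow(g)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(target = target, dct2 = dct2,
                 replicates = reps, summary = summ),
            class = "bigih_ddct")
}

#' One-tailed pooled-variance t test
#'
#' Equal-variance two-sample t statistic with
#' `df = n_a + n_b - 2`, tested one-tailed in the direction
#' `mean(a) > mean(b)`. When the pooled variance is zero and the means are
#' equal, the comparison is degenerate and `p = 0.5` is returned with a
#' warning.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return List with `statistic`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
one_tailed_equal_variance_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each group needs at least 2 values")
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  delta <- mean(a) - mean(b)
  if (sp2 == 0) {
    if (delta == 0) {
      warning("zero pooled variance with equal means; degenerate p = 0.5")
      return(list(statistic = 0, df = df, p_value = 0.5,
                  mean_a = mean(a), mean_b = mean(b)))
    }
    t <- sign(delta) * Inf
  } else {
    t <- delta / sqrt(sp2 * (1 / na + 1 / nb))
  }
  list(statistic = t, df = df,
       p_value = stats::pt(t, df, lower.tail = FALSE),
       mean_a = mean(a), mean_b = mean(b))
}

#' Read a qPCR Ct table
#'
#' @param path TSV with columns `sample`, `group`, `target`, `ct_target`,
#'   `ct_reference`.
#' @return Data frame.
#' @export
read_ct_tsv <- function(path) {
  ct <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample", "group", "target", "ct_target", "ct_reference")
  if (!all(need %in% names(ct))) {
    stop("Ct table needs columns: ", paste(need, collapse = ", "))
  }
  ct
}
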