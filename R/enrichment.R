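#' Right-tailed Fisher exact probability of a gene-set overlap
#'
#' Probability, under random sampling without replacement, of observing at
#' least the seen overlap between a gene set of size `n` and an annotation
#' of size `K` in a universe of `N` genes: the hypergeometric upper tail
#' including the observed count,
#' `p = sum_{i=k}^{min(n,K)} C(K,i) C(N-K,n-i) / C(N,n)`.
#'
#' @param k Observed overlap.
#' @param n Gene-set size.
#' @param K Annotation size within the universe.
#' @param N Universe size.
#' @return p-value in `(0, 1]`.
#' @export
fisher_right_tail <- function(k, n, K, N) {
  if (any(c(k, n, K, N) < 0) || k > min(n, K) || n > N || K > N) {
    stop("invalid contingency counts: need 0 <= k <= min(n, K) and n, K <= N")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Rank annotations by enrichment in a gene set
#'
#' Computes the right-tailed Fisher p-value of every annotation set against
#' the gene set within the given universe and ranks the annotations by
#' ascending p-value (ties broken by descending overlap, then by name).
#' Annotations with no overlap are omitted. An annotation named in
#' `exclude` — typically the seed category from which the genes were
#' selected in the first place — is dropped before ranking.
#'
#' @param gene_set Character vector of gene symbols.
#' @param annotations Named list of character vectors (e.g. [read_gmt()]).
#' @param universe Character vector of all measured genes.
#' @param exclude Optional character vector of annotation names to drop.
#' @param adjust Multiple-testing adjustment for the reported `p_adjusted`
#'   column: `"none"` (default; ranking always uses the raw p-value) or
#'   any method accepted by [stats::p.adjust()], e.g. `"BH"`.
#' @return Data frame with columns `set_name`, `k`, `n`, `K`, `N`,
#'   `p_value`, `p_adjusted`, `rank`.
#' @export
rank_functions <- function(gene_set, annotations, universe, exclude = NULL,
                           adjust = "none") {
  universe <- unique(normalize_symbol(universe))
  if (length(universe) == 0) stop("empty universe")
  gene_set <- unique(normalize_symbol(gene_set))
  outside <- setdiff(gene_set, universe)
  if (length(outside)) {
    warning(length(outside), " gene(s) outside the universe dropped")
    gene_set <- intersect(gene_set, universe)
  }
  if (!is.null(exclude)) annotations <- annotations[setdiff(names(annotations), exclude)]
  n <- length(gene_set)
  N <- length(universe)
  rows <- lapply(names(annotations), function(nm) {
    ann <- intersect(unique(normalize_symbol(annotations[[nm]])), universe)
    k <- length(intersect(ann, gene_set))
    if (k < 1) return(NULL)
    data.frame(set_name = nm, k = k, n = n, K = length(ann), N = N,
               p_value = fisher_right_tail(k, n, length(ann), N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(set_name = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p_value = numeric(),
                      p_adjusted = numeric(), rank = integer(),
                      stringsAsFactors = FALSE))
  }
  out$p_adjusted <- if (identical(adjust, "none")) out$p_value else
    stats::p.adjust(out$p_value, method = adjust)
  out <- out[order(out$p_value, -out$k, out$set_name), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Rank shift between two enrichment rankings
#'
#' For each annotation, `shift = rank_before - rank_after`, so a positive
#' shift means the annotation moved up once the gene set changed (e.g. from
#' the full GOI to the top two hierarchy tiers). Annotations present in
#' only one ranking get an `NA` shift and `in_both = FALSE`.
#'
#' @param before,after Data frames from [rank_functions()].
#' @return Data frame with columns `set_name`, `rank_before`, `rank_after`,
#'   `shift`, `in_both`.
#' @export
rank_shift <- function(before, after) {
  all_sets <- union(before$set_name, after$set_name)
  rb <- stats::setNames(before$rank, before$set_name)[all_sets]
  ra <- stats::setNames(after$rank, after$set_name)[all_sets]
  out <- data.frame(set_name = all_sets,
                    rank_before = as.integer(unname(rb)),
                    rank_after = as.integer(unname(ra)),
                    shift = as.integer(unname(rb) - unname(ra)),
                    in_both = !is.na(rb) & !is.na(ra),
                    stringsAsFactors = FALSE)
  out <- out[order(out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-reference hierarchy tiers with an annotation
#'
#' For each hierarchy tier, counts the annotated members and, when signed
#' fold changes are available, the fractions of annotated members up- and
#' down-regulated; also aggregates the top two (primary + secondary) tiers.
#'
#' @param gih Data frame with columns `gene`, `tier` and optionally
#'   `signed_fc` (e.g. from [build_hierarchy()] or [tbi_gih()]).
#' @param annotation Character vector of annotated gene symbols.
#' @return List with `by_tier` (data frame: `tier`, `n_tier`,
#'   `n_annotated`, `frac_up`, `frac_down`), `members` (named list of
#'   annotated genes per tier), `n_annotated` (total annotated genes in the
#'   hierarchy), and `top2` (list: `n_genes`, `n_annotated`, `fraction`).
#' @export
cross_reference_tiers <- function(gih, annotation) {
  annotation <- unique(normalize_symbol(annotation))
  gih$gene <- normalize_symbol(gih$gene)
  tiers <- c("primary", "secondary", "peripheral", "orphan")
  has_fc <- "signed_fc" %in% names(gih)
  rows <- lapply(tiers, function(t) {
    sub <- gih[gih$tier == t, , drop = FALSE]
    ann <- sub[sub$gene %in% annotation, , drop = FALSE]
    fu <- fd <- NA_real_
    if (has_fc && nrow(ann)) {
      fu <- mean(ann$signed_fc > 0)
      fd <- mean(ann$signed_fc < 0)
    }
    data.frame(tier = t, n_tier = nrow(sub), n_annotated = nrow(ann),
               frac_up = fu, frac_down = fd, stringsAsFactors = FALSE)
  })
  by_tier <- do.call(rbind, rows)
  members <- lapply(tiers, function(t) {
    sort(intersect(gih$gene[gih$tier == t], annotation))
  })
  names(members) <- tiers
  top2 <- gih[gih$tier %in% c("primary", "secondary"), , drop = FALSE]
  n_top2_ann <- sum(top2$gene %in% annotation)
  list(by_tier = by_tier,
       members = members,
       n_annotated = sum(by_tier$n_annotated),
       top2 = list(n_genes = nrow(top2), n_annotated = n_top2_ann,
                   fraction = if (nrow(top2)) n_top2_ann / nrow(top2) else NA_real_))
}
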