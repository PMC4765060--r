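#' Candidate pool for genes-of-interest selection
#'
#' The pool of genes eligible to become genes of interest (GOI) on a side:
#' the genes that changed uniquely on that side plus all genes that changed
#' differently between the sides.
#'
#' @param btab A [bilateral_table()] data frame.
#' @param side `"ipsilateral"` or `"contralateral"`.
#' @return Character vector of normalized gene symbols.
#' @export
candidate_pool <- function(btab, side = c("ipsilateral", "contralateral")) {
  side <- match.arg(side)
  uniq <- if (side == "ipsilateral") "unique_ipsi" else "unique_contra"
  sort(btab$gene[btab$partition %in% c(uniq, "common_different")])
}

#' Assemble genes of interest with overlap accounting
#'
#' Starting from a seed set (typically the changed-differently genes), each
#' source (a canonical pathway gene list, then interaction-network gene
#' lists, in the order given) contributes its members intersected with the
#' candidate pool. For every source the accounting records the number of
#' pool genes found (`total_found`), how many were already in the running
#' union (`overlap_with_previous`), and the net new genes (`net_new`).
#' The final GOI set is the seed plus all contributions; it does not depend
#' on source order, although the per-source accounting does.
#'
#' @param seed Character vector of seed gene symbols.
#' @param sources Named list of character vectors, processed in order.
#' @param pool Optional character vector restricting source contributions;
#'   `NULL` (default) applies no restriction, for sources that are already
#'   pool-filtered.
#' @return List of class `"bigih_goi"` with elements `genes` (sorted
#'   character vector), `accounting` (data frame: `source`, `total_found`,
#'   `overlap_with_previous`, `net_new`), and `provenance` (named list
#'   mapping each gene to the seed/source names that contained it).
#' @export
assemble_goi <- function(seed, sources, pool = NULL) {
  if (length(sources) && (is.null(names(sources)) || any(!nzchar(names(sources))))) {
    stop("sources must be a named list")
  }
  if (anyDuplicated(names(sources))) stop("duplicate source names")
  seed <- unique(normalize_symbol(seed))
  if (!is.null(pool)) pool <- unique(normalize_symbol(pool))
  running <- seed
  prov <- stats::setNames(lapply(seed, function(g) "seed"), seed)
  acc <- data.frame(source = character(), total_found = integer(),
                    overlap_with_previous = integer(), net_new = integer(),
                    stringsAsFactors = FALSE)
  for (nm in names(sources)) {
    members <- unique(normalize_symbol(sources[[nm]]))
    found <- if (is.null(pool)) members else intersect(members, pool)
    overlap <- sum(found %in% running)
    new_genes <- setdiff(found, running)
    acc <- rbind(acc, data.frame(source = nm,
                                 total_found = length(found),
                                 overlap_with_previous = overlap,
                                 net_new = length(new_genes),
                                 stringsAsFactors = FALSE))
    for (g in found) prov[[g]] <- c(prov[[g]], nm)
    running <- c(running, new_genes)
  }
  structure(list(genes = sort(running), accounting = acc,
                 provenance = prov[sort(names(prov))]),
            class = "bigih_goi")
}

#' @export
print.bigih_goi <- function(x, ...) {
  cat("Genes of interest:", length(x$genes), "genes from",
      nrow(x$accounting), "source(s) plus seed\n")
  print(x$accounting)
  invisible(x)
}
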