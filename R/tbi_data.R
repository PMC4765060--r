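#' Bundled reference dataset: bilateral cell-death gene response to TBI
#'
#' The package ships the printed result tables of a unilateral controlled
#' cortical impact (CCI) microarray study in rat, in which cell-death genes
#' were profiled 24 h post-injury in ipsilateral, contralateral and naive
#' brain tissue. These plain-text fixtures drive the worked examples and
#' the regression checks of the ratio, GOI-assembly and tier
#' cross-referencing stages.
#'
#' @name tbi_reference_data
#' @keywords datasets
NULL

tbi_extdata <- function(file) {
  path <- system.file("extdata", file, package = "bigih")
  if (!nzchar(path)) stop("bundled file not found: ", file)
  path
}

tbi_side <- function(side) {
  match.arg(side, c("ipsilateral", "contralateral"))
}

#' Changed-differently gene table
#'
#' The 73 cell-death genes that changed on both sides of the brain with a
#' bilateral ratio magnitude above 2: signed ipsilateral and contralateral
#' fold changes versus naive, and the published ratio (3-decimal
#' precision).
#'
#' @return Data frame with columns `gene` (normalized), `fc_ipsi`,
#'   `fc_contra`, `ratio_printed`.
#' @export
tbi_changed_differently <- function() {
  df <- utils::read.delim(tbi_extdata("changed_differently.tsv"),
                          stringsAsFactors = FALSE)
  data.frame(gene = normalize_symbol(df$gene),
             fc_ipsi = df$fc_ipsi, fc_contra = df$fc_contra,
             ratio_printed = df$ratio, stringsAsFactors = FALSE)
}

#' Genes-of-interest source lists
#'
#' The published GOI source lists for one side: the apoptosis-signaling
#' canonical pathway GOI followed by the GOI found in each of the six
#' top-scoring interaction networks, in publication order. These lists are
#' already intersected with the side's candidate pool, so they are
#' assembled with `pool = NULL`.
#'
#' @param side `"ipsilateral"` or `"contralateral"`.
#' @return Named list of character vectors, in assembly order.
#' @export
tbi_goi_sources <- function(side = c("ipsilateral", "contralateral")) {
  side <- tbi_side(match.arg(side))
  file <- if (side == "ipsilateral") "goi_sources_ipsi.gmt" else "goi_sources_contra.gmt"
  read_gmt(tbi_extdata(file))
}

#' Published gene interaction hierarchy
#'
#' The ranked GOI for one side: 170 genes (ipsilateral; main component of
#' 145) or 115 genes (contralateral; main component of 78), each with its
#' signed fold change and tier. Tier membership depends on a proprietary
#' interaction knowledge base and is therefore shipped as data rather than
#' recomputed.
#'
#' @param side `"ipsilateral"` or `"contralateral"`.
#' @return Data frame with columns `gene` (normalized), `signed_fc`,
#'   `tier` (`primary`, `secondary`, `peripheral`, `orphan`).
#' @export
tbi_gih <- function(side = c("ipsilateral", "contralateral")) {
  side <- tbi_side(match.arg(side))
  file <- if (side == "ipsilateral") "gih_ipsi.tsv" else "gih_contra.tsv"
  df <- utils::read.delim(tbi_extdata(file), stringsAsFactors = FALSE)
  data.frame(gene = normalize_symbol(df$gene),
             signed_fc = df$fold_change, tier = df$tier,
             stringsAsFactors = FALSE)
}

#' Published cell-cycle annotation of the hierarchies
#'
#' The genes of each hierarchy annotated to the cell-cycle upper-level
#' biological function (74 ipsilateral, 47 contralateral).
#'
#' @param side `"ipsilateral"` or `"contralateral"`.
#' @return Character vector of normalized gene symbols.
#' @export
tbi_cell_cycle_genes <- function(side = c("ipsilateral", "contralateral")) {
  side <- tbi_side(match.arg(side))
  file <- if (side == "ipsilateral") "cell_cycle_ipsi.txt" else "cell_cycle_contra.txt"
  normalize_symbol(readLines(tbi_extdata(file), warn = FALSE))
}
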