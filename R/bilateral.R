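#' Linearize a signed fold change
#'
#' Maps the signed fold-change convention (magnitude >= 1, sign = direction)
#' onto the positive ratio scale: `fc` itself for increases, `1/|fc|` for
#' decreases. This is the bridge between the signed convention used in
#' reported tables and the ratio algebra.
#'
#' @param fc Numeric vector of signed fold changes with `|fc| >= 1`.
#' @return Positive numeric vector.
#' @export
linearize <- function(fc) {
  bad <- !is.na(fc) & abs(fc) < 1
  if (any(bad)) {
    stop("signed fold change magnitude below 1: ",
         paste(utils::head(fc[bad], 5), collapse = ", "))
  }
  ifelse(fc > 0, fc, -1 / fc)
}

#' Ipsilateral/contralateral fold-change ratio
#'
#' Compares how strongly a gene changed on the injured (ipsilateral) side
#' versus the mirror (contralateral) side. Both signed fold changes are
#' linearized; the ratio `r = linearize(fc_i) / linearize(fc_c)` is
#' returned as `r` when `r >= 1` and as `-1/r` otherwise, so the result is
#' itself a signed fold change of relative expression: magnitude >= 1, with
#' a negative sign exactly when the gene's relative expression is lower
#' ipsilaterally than contralaterally. This single rule reproduces each of
#' the five piecewise case formulas used in bilateral reporting (both up
#' with ipsi larger; both down, either side more extreme; up ipsi / down
#' contra; down ipsi / up contra) and also covers the remaining case (both
#' up, contra larger) that a five-case list omits.
#'
#' @param fc_i,fc_c Signed fold changes for the ipsilateral and
#'   contralateral sides (vectorized; `|fc| >= 1`).
#' @return Numeric vector of signed ratios, `|ratio| >= 1`.
#' @export
bilateral_ratio <- function(fc_i, fc_c) {
  r <- linearize(fc_i) / linearize(fc_c)
  ifelse(r >= 1, r, -1 / r)
}

#' Classify a gene's bilateral expression pattern
#'
#' Genes changed on a single side are `unique_ipsi` / `unique_contra`;
#' genes changed on both sides are `common_different` when the magnitude of
#' the bilateral ratio exceeds `ratio_cutoff` (strictly) and
#' `common_similar` otherwise. Pass `NA` for a side on which the gene did
#' not pass selection.
#'
#' @param fc_i,fc_c Signed fold changes or `NA` (vectorized).
#' @param ratio_cutoff Strict threshold on `|ratio|` (default 2).
#' @return Character vector with values `unique_ipsi`, `unique_contra`,
#'   `common_similar`, `common_different`.
#' @export
classify_gene <- function(fc_i, fc_c, ratio_cutoff = 2) {
  if (length(fc_i) != length(fc_c)) stop("fc_i and fc_c lengths differ")
  both_na <- is.na(fc_i) & is.na(fc_c)
  if (any(both_na)) {
    stop("gene with neither side defined at position ",
         paste(which(both_na), collapse = ", "))
  }
  out <- character(length(fc_i))
  out[!is.na(fc_i) & is.na(fc_c)] <- "unique_ipsi"
  out[is.na(fc_i) & !is.na(fc_c)] <- "unique_contra"
  both <- !is.na(fc_i) & !is.na(fc_c)
  if (any(both)) {
    ratio <- bilateral_ratio(fc_i[both], fc_c[both])
    out[both] <- ifelse(abs(ratio) > ratio_cutoff,
                        "common_different", "common_similar")
  }
  out
}

#' Build the bilateral classification table
#'
#' Combines per-side changed-gene records into one row per gene with both
#' signed fold changes, the bilateral ratio (defined only when both sides
#' changed), the partition class, and per-side directions. Rows where both
#' sides increased but the contralateral change is the larger one are
#' flagged `extrapolated`, as that configuration falls outside the five
#' piecewise case formulas and is handled by the generalized rule.
#'
#' @param de Data frame as returned by [select_changed_genes()]: columns
#'   `gene`, `side`, `signed_fc`.
#' @param ratio_cutoff Strict threshold on `|ratio|` for the
#'   changed-differently class.
#' @return Data frame with columns `gene`, `fc_i`, `fc_c`, `ratio`,
#'   `partition`, `direction_i`, `direction_c`, `extrapolated`.
#' @export
bilateral_table <- function(de, ratio_cutoff = 2) {
  need <- c("gene", "side", "signed_fc")
  if (!all(need %in% names(de))) {
    stop("de needs columns: ", paste(need, collapse = ", "))
  }
  de$gene <- normalize_symbol(de$gene)
  ipsi <- de[de$side == "ipsilateral", ]
  contra <- de[de$side == "contralateral", ]
  if (anyDuplicated(ipsi$gene) || anyDuplicated(contra$gene)) {
    stop("duplicate gene records within a side")
  }
  genes <- sort(union(ipsi$gene, contra$gene))
  fc_i <- unname(stats::setNames(ipsi$signed_fc, ipsi$gene)[genes])
  fc_c <- unname(stats::setNames(contra$signed_fc, contra$gene)[genes])
  both <- !is.na(fc_i) & !is.na(fc_c)
  ratio <- rep(NA_real_, length(genes))
  ratio[both] <- bilateral_ratio(fc_i[both], fc_c[both])
  dirn <- function(fc) ifelse(is.na(fc), "none", ifelse(fc > 0, "up", "down"))
  out <- data.frame(
    gene = genes,
    fc_i = unname(fc_i),
    fc_c = unname(fc_c),
    ratio = ratio,
    partition = classify_gene(unname(fc_i), unname(fc_c), ratio_cutoff),
    direction_i = dirn(unname(fc_i)),
    direction_c = dirn(unname(fc_c)),
    extrapolated = both & !is.na(fc_i) & !is.na(fc_c) &
      fc_i > 0 & fc_c > 0 & fc_c > fc_i,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Summarize the bilateral partition
#'
#' Counts and integer percentages for each partition cell, the direction
#' breakdown within the unique cells, the similar/different split within
#' the common cell, and the number of changed-differently genes with a
#' negative ratio (relative expression lower ipsilaterally).
#'
#' @param btab A [bilateral_table()] data frame.
#' @return List of class `"bigih_partition_summary"`.
#' @export
partition_summary <- function(btab) {
  cnt <- function(x) sum(x, na.rm = TRUE)
  pct <- function(num, den) if (den > 0) as.integer(round(100 * num / den)) else 0L
  cell <- function(p) btab[btab$partition == p, , drop = FALSE]
  ui <- cell("unique_ipsi"); uc <- cell("unique_contra")
  cs <- cell("common_similar"); cd <- cell("common_different")
  n_common <- nrow(cs) + nrow(cd)
  out <- list(
    total = nrow(btab),
    counts = c(unique_ipsi = nrow(ui), unique_contra = nrow(uc),
               common_similar = nrow(cs), common_different = nrow(cd)),
    unique_ipsi = list(
      up = cnt(ui$direction_i == "up"), down = cnt(ui$direction_i == "down"),
      pct_up = pct(cnt(ui$direction_i == "up"), nrow(ui)),
      pct_down = pct(cnt(ui$direction_i == "down"), nrow(ui))),
    unique_contra = list(
      up = cnt(uc$direction_c == "up"), down = cnt(uc$direction_c == "down"),
      pct_up = pct(cnt(uc$direction_c == "up"), nrow(uc)),
      pct_down = pct(cnt(uc$direction_c == "down"), nrow(uc))),
    common = list(
      n = n_common,
      similar = nrow(cs), different = nrow(cd),
      pct_similar = pct(nrow(cs), n_common),
      pct_different = pct(nrow(cd), n_common),
      similar_up = cnt(cs$direction_i == "up" & cs$direction_c == "up"),
      similar_down = cnt(cs$direction_i == "down" & cs$direction_c == "down"),
      different_negative_ratio = cnt(cd$ratio < 0))
  )
  class(out) <- "bigih_partition_summary"
  out
}

#' @export
print.bigih_partition_summary <- function(x, ...) {
  cat("Bilateral partition of", x$total, "changed genes\n")
  cat(sprintf("  unique ipsilateral : %d (%d%% up)\n",
              x$counts[["unique_ipsi"]], x$unique_ipsi$pct_up))
  cat(sprintf("  unique contralateral: %d (%d%% down)\n",
              x$counts[["unique_contra"]], x$unique_contra$pct_down))
  cat(sprintf("  common: %d; %d similar (%d%%), %d different (%d%%, %d with negative ratio)\n",
              x$common$n, x$common$similar, x$common$pct_similar,
              x$common$different, x$common$pct_different,
              x$common$different_negative_ratio))
  invisible(x)
}

#' Write a bilateral table as TSV
#'
#' Fold changes and ratios are rounded to three decimals to match the
#' reporting precision of bilateral tables; in-memory values keep full
#' precision.
#'
#' @param btab A [bilateral_table()] data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bilateral_tsv <- function(btab, path) {
  out <- btab
  for (cl in c("fc_i", "fc_c", "ratio")) out[[cl]] <- round(out[[cl]], 3)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
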