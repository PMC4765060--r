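#' Normalize gene symbols
#'
#' Gene identity throughout the package is the uppercased, whitespace-trimmed
#' symbol with any parenthetical annotation removed, so that mixed-case
#' variants of the same symbol (e.g. `"Slpi"` and `"SLPI"`) and annotated
#' forms such as `"CDK1 (Cdc2)"` collapse to one identifier. No alias or
#' orthology resolution is attempted.
#'
#' @param x Character vector of raw gene symbols.
#' @return Character vector of normalized symbols, same length as `x`.
#' @examples
#' normalize_symbol(c("Slpi", "SPP1", "CDK1 (Cdc2)"))
#' @export
normalize_symbol <- function(x) {
  if (!is.character(x)) stop("gene symbols must be character")
  out <- sub("\\s*\\(.*$", "", trimws(x))
  out <- toupper(trimws(out))
  if (any(!nzchar(out))) {
    stop("empty gene symbol at position ",
         paste(which(!nzchar(out)), collapse = ", "))
  }
  out
}

#' Analysis configuration
#'
#' Bundles the tunable parameters of the pipeline with their defaults: the
#' fold-change selection cutoff and ipsilateral/contralateral ratio cutoff
#' (both 2, on the signed fold-change magnitude scale), the presence rule,
#' the fractions of the main network component that define the primary and
#' secondary hierarchy tiers, and the detection-call parameters (`tau`,
#' `alpha1`, `alpha2`, defaults from standard MAS5 practice).
#'
#' @param fold_change_cutoff Minimum `|signed fold change|` for a gene to
#'   count as changed on a side. Must be > 1.
#' @param ratio_cutoff Genes changed on both sides with
#'   `|ratio| > ratio_cutoff` are classified as changed differently.
#' @param presence_rule `"either_side_all"` (default): a gene passes the
#'   presence gate when it is called present in every sample of the
#'   ipsilateral group or in every sample of the contralateral group; the
#'   same gate applies to both sides. `"per_side_all"` requires presence in
#'   all samples of the side being selected.
#' @param tier_primary_fraction,tier_secondary_fraction Fractions of the
#'   other main-component genes defining the primary and secondary tier
#'   cutoffs; `0 < secondary < primary < 1`.
#' @param tau Discrimination-score threshold for the detection test.
#' @param alpha1,alpha2 Detection p-value cutoffs: present if `p < alpha1`,
#'   marginal if `alpha1 <= p < alpha2`, absent otherwise.
#' @param seed Optional integer seed recorded for simulation runs.
#' @return A list of class `"bigih_config"`.
#' @export
analysis_config <- function(fold_change_cutoff = 2,
                            ratio_cutoff = 2,
                            presence_rule = c("either_side_all", "per_side_all"),
                            tier_primary_fraction = 0.10,
                            tier_secondary_fraction = 0.05,
                            tau = 0.015,
                            alpha1 = 0.04,
                            alpha2 = 0.06,
                            seed = NULL) {
  presence_rule <- match.arg(presence_rule)
  if (fold_change_cutoff <= 1) stop("fold_change_cutoff must be > 1")
  if (ratio_cutoff <= 1) stop("ratio_cutoff must be > 1")
  if (!(tier_secondary_fraction > 0 &&
        tier_secondary_fraction < tier_primary_fraction &&
        tier_primary_fraction < 1)) {
    stop("need 0 < tier_secondary_fraction < tier_primary_fraction < 1")
  }
  if (!(alpha1 > 0 && alpha1 < alpha2 && alpha2 < 1)) {
    stop("need 0 < alpha1 < alpha2 < 1")
  }
  structure(list(fold_change_cutoff = fold_change_cutoff,
                 ratio_cutoff = ratio_cutoff,
                 presence_rule = presence_rule,
                 tier_primary_fraction = tier_primary_fraction,
                 tier_secondary_fraction = tier_secondary_fraction,
                 tau = tau, alpha1 = alpha1, alpha2 = alpha2,
                 seed = seed),
            class = "bigih_config")
}

#' Construct an expression matrix with group labels
#'
#' @param values Numeric matrix, genes in rows (rownames = symbols),
#'   samples in columns (colnames = sample labels). Values are non-negative
#'   summarized intensities.
#' @param groups Named character vector mapping every sample label to one of
#'   `"ipsilateral"`, `"contralateral"`, `"naive"`.
#' @return A list of class `"bigih_expr"` with elements `values` and
#'   `groups`; gene symbols are normalized.
#' @export
expression_matrix <- function(values, groups) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values needs gene rownames and sample colnames")
  }
  rownames(values) <- normalize_symbol(rownames(values))
  if (anyDuplicated(rownames(values))) stop("duplicate gene rows")
  if (anyDuplicated(colnames(values))) stop("duplicate sample labels")
  if (any(values < 0)) stop("intensities must be non-negative")
  nm <- if (is.null(names(groups))) colnames(values) else names(groups)
  groups <- vapply(as.character(groups), function(g) {
    match.arg(g, c("ipsilateral", "contralateral", "naive"))
  }, character(1), USE.NAMES = FALSE)
  names(groups) <- nm
  missing <- setdiff(colnames(values), names(groups))
  if (length(missing)) {
    stop("samples missing from group map: ", paste(missing, collapse = ", "))
  }
  groups <- groups[colnames(values)]
  structure(list(values = values, groups = groups), class = "bigih_expr")
}

#' Read a gene-by-sample expression table
#'
#' Tab-separated file with gene symbols in the first column and one column
#' per sample. Duplicate gene rows (after symbol normalization) are
#' collapsed by their arithmetic mean with a warning.
#'
#' @param path Path to the TSV file.
#' @param group_map Named character vector assigning each sample label to a
#'   group (`ipsilateral`, `contralateral` or `naive`).
#' @return A `"bigih_expr"` object.
#' @export
read_expression_tsv <- function(path, group_map) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(raw) < 2) stop("expression table needs a gene column and samples")
  genes <- normalize_symbol(raw[[1]])
  samples <- colnames(raw)[-1]
  vals <- matrix(NA_real_, nrow = nrow(raw), ncol = length(samples),
                 dimnames = list(NULL, samples))
  for (j in seq_along(samples)) {
    col <- raw[[j + 1]]
    v <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(v) | is.na(col) | col == "NA")
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                   col[bad[1]], bad[1], samples[j]))
    }
    vals[, j] <- v
  }
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warning(length(dup), " duplicated gene row(s) collapsed by mean: ",
            paste(utils::head(dup, 5), collapse = ", "))
    vals <- rowsum(vals, genes) / as.vector(table(genes)[sort(unique(genes))])
    genes <- sort(unique(genes))
  }
  rownames(vals) <- genes
  missing <- setdiff(samples, names(group_map))
  if (length(missing)) {
    stop("samples missing from group_map: ", paste(missing, collapse = ", "))
  }
  expression_matrix(vals, group_map[samples])
}

#' Write an expression matrix to TSV
#'
#' @param x A `"bigih_expr"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path) {
  stopifnot(inherits(x, "bigih_expr"))
  df <- data.frame(gene = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. Members are
#' normalized; duplicates within a line are dropped.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors with a `"description"`
#'   attribute (named character vector of per-set descriptions).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("GMT line %d has %d field(s); need name, description and at least one member",
                   i, length(fields)))
    }
    name <- fields[1]
    if (name %in% names(sets)) stop("duplicate set name '", name, "' at line ", i)
    members <- unique(normalize_symbol(fields[-(1:2)]))
    sets[[name]] <- members
    desc[name] <- fields[2]
  }
  attr(sets, "description") <- desc
  sets
}

#' Write a gene-set collection as GMT
#'
#' @param sets Named list of character vectors (a `"description"` attribute,
#'   if present, supplies the second column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("sets must be a named list")
  }
  desc <- attr(sets, "description")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else ""
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Build an undirected, deduplicated edge list
#'
#' @param from,to Character vectors of endpoint gene symbols.
#' @return Data frame with columns `from`, `to` (normalized, `from <= to`
#'   lexicographically, one row per unordered pair). Self-loops are removed
#'   and counted in a warning.
#' @export
edge_list <- function(from, to) {
  from <- normalize_symbol(from)
  to <- normalize_symbol(to)
  self <- from == to
  if (any(self)) {
    warning(sum(self), " self-loop(s) removed")
    from <- from[!self]
    to <- to[!self]
  }
  a <- pmin(from, to)
  b <- pmax(from, to)
  keep <- !duplicated(paste(a, b, sep = "\r"))
  out <- data.frame(from = a[keep], to = b[keep], stringsAsFactors = FALSE)
  out <- out[order(out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a gene interaction edge list
#'
#' Accepts two-column whitespace- or tab-separated files (`A B`) and SIF
#' lines (`A relation B [C ...]`); the relation token is ignored and
#' multiple targets on a SIF line each form an edge with the source. The
#' result is undirected and deduplicated; self-loops are dropped with a
#' warning.
#'
#' @param path Path to the edge list file.
#' @return Data frame with columns `from`, `to` (see [edge_list()]).
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && tolower(gsub("[\t ]+", " ", trimws(lines[1]))) == "from to") {
    lines <- lines[-1]  # header emitted by write_edge_list
  }
  from <- character()
  to <- character()
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "[\t ]+")[[1]]
    if (length(tok) < 2) {
      stop(sprintf("edge list line %d has a single token: '%s'", i, lines[i]))
    }
    if (length(tok) == 2) {
      from <- c(from, tok[1]); to <- c(to, tok[2])
    } else {
      # SIF: source, relation, one or more targets
      from <- c(from, rep(tok[1], length(tok) - 2))
      to <- c(to, tok[-(1:2)])
    }
  }
  edge_list(from, to)
}

#' Write an edge list as two-column TSV
#'
#' @param edges Data frame with columns `from`, `to`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  utils::write.table(edges[, c("from", "to")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
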