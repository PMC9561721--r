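#' Read a per-study differential-expression table
#'
#' Parses a GEO2R/GREIN-style differential-expression export: a delimited
#' text file with a header row containing at least a gene-symbol column, a
#' p-value column and a signed fold-change (direction) column. Rows with a
#' missing or unparseable gene symbol or p-value, or a p-value outside
#' \[0, 1\], are dropped and counted; the function never silently truncates.
#'
#' @param path Path to a tab- or comma-separated file with a header row.
#'   `.csv` files are read comma-separated; anything else defaults to tabs
#'   unless `format_spec$delimiter` says otherwise.
#' @param format_spec Named list mapping roles to column names:
#'   `gene_col` (default `"Gene.symbol"`), `pval_col` (default `"P.Value"`),
#'   `lfc_col` (default `"logFC"`), and optionally `delimiter`.
#' @param study_id Label attached to the result; defaults to the file name
#'   without extension.
#'
#' @return A `deg_table`: a data frame with columns `gene`, `p_value`,
#'   `direction`, plus attributes `study_id` and `n_dropped`.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("Gene.symbol\tP.Value\tlogFC",
#'              "Gfap\t0.001\t1.2", "BDNF\t0.04\t-0.8"), tf)
#' read_de_table(tf)
read_de_table <- function(path,
                          format_spec = list(),
                          study_id = NULL) {
  if (!file.exists(path)) {
    stop("DE table file not found: ", path, call. = FALSE)
  }
  spec <- utils::modifyList(
    list(gene_col = "Gene.symbol", pval_col = "P.Value", lfc_col = "logFC",
         delimiter = NULL),
    format_spec
  )
  sep <- spec$delimiter %||%
    if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           comment.char = "", check.names = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  for (role in c("gene_col", "pval_col", "lfc_col")) {
    col <- spec[[role]]
    if (!col %in% names(raw)) {
      stop("Column '", col, "' (", role, ") not found in ", path,
           "; available columns: ", paste(names(raw), collapse = ", "),
           call. = FALSE)
    }
  }
  gene <- norm_symbols(raw[[spec$gene_col]])
  p    <- suppressWarnings(as.numeric(raw[[spec$pval_col]]))
  lfc  <- suppressWarnings(as.numeric(raw[[spec$lfc_col]]))
  lfc[is.na(lfc)] <- 0  # no direction evidence

  bad_gene <- is.na(gene) | gene == "" | gene == "NA"
  bad_p    <- is.na(p) | p < 0 | p > 1
  keep <- !(bad_gene | bad_p)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    sp_log("rows_dropped", path = path, n_dropped = n_dropped,
           missing_gene = sum(bad_gene), bad_pvalue = sum(bad_p & !bad_gene))
  }
  if (!any(keep)) {
    stop("No parseable rows in ", path, call. = FALSE)
  }
  out <- data.frame(gene = gene[keep], p_value = p[keep],
                    direction = lfc[keep], stringsAsFactors = FALSE)
  structure(out,
            study_id = study_id %||% tools::file_path_sans_ext(basename(path)),
            n_dropped = n_dropped,
            class = c("deg_table", "data.frame"))
}

#' Construct a deg_table from vectors
#'
#' Programmatic constructor used by the simulator and by tests; applies the
#' same invariants as [read_de_table()] (symbols upper-cased and stripped,
#' rows with missing p or gene dropped and counted).
#'
#' @param gene Character vector of gene symbols.
#' @param p_value Numeric p-values in \[0, 1\].
#' @param direction Signed numeric direction values (e.g. logFC).
#' @param study_id Label for the study.
#' @return A `deg_table`.
#' @export
deg_table <- function(gene, p_value, direction, study_id = "study") {
  gene <- norm_symbols(gene)
  direction <- as.numeric(direction)
  direction[is.na(direction)] <- 0
  keep <- !(is.na(gene) | gene == "" | is.na(p_value) |
              p_value < 0 | p_value > 1)
  structure(
    data.frame(gene = gene[keep], p_value = as.numeric(p_value)[keep],
               direction = direction[keep], stringsAsFactors = FALSE),
    study_id = study_id, n_dropped = sum(!keep),
    class = c("deg_table", "data.frame")
  )
}

#' Signed dysregulation scores (sign1) from a DE table
#'
#' Collapses a differential-expression table to one signed score per gene:
#' `sign1 = -log10(max(p, p_floor)) * sign(direction)`. The magnitude grows
#' as the p-value shrinks and the sign carries the direction of change versus
#' control (positive = up). Duplicate symbols (multiple probes) are resolved
#' by keeping the row with the smallest p-value — the strongest evidence —
#' with ties going to the first occurrence in input order.
#'
#' @param table A `deg_table`.
#' @param p_floor Clamp for p = 0 (and anything smaller) before the log;
#'   default `1e-300`, giving a maximal |sign1| of 300.
#' @return A `signed_scores` data frame with columns `gene`, `sign1` and
#'   attributes `study_id`, `n_duplicates_removed`.
#' @export
to_signed_scores <- function(table, p_floor = 1e-300) {
  stopifnot(p_floor > 0, p_floor < 1)
  ord <- order(table$p_value)  # stable: ties keep input order
  tab <- table[ord, , drop = FALSE]
  keep <- !duplicated(tab$gene)
  n_dup <- sum(!keep)
  tab <- tab[keep, , drop = FALSE]
  # restore input order of the surviving rows
  tab <- tab[order(ord[keep]), , drop = FALSE]
  sign1 <- neg_log10(tab$p_value, p_floor) * sign(tab$direction)
  if (n_dup > 0) {
    sp_log("duplicates_removed", study_id = attr(table, "study_id"),
           n = n_dup)
  }
  signed_scores(tab$gene, sign1,
                study_id = attr(table, "study_id") %||% "study",
                n_duplicates_removed = n_dup)
}

#' Construct a signed_scores object
#'
#' @param gene Character vector of unique gene symbols.
#' @param sign1 Finite signed scores (−log10 p times direction sign).
#' @param study_id Label.
#' @param n_duplicates_removed Bookkeeping count carried as an attribute.
#' @return A `signed_scores` data frame.
#' @export
signed_scores <- function(gene, sign1, study_id = "study",
                          n_duplicates_removed = 0L) {
  gene <- norm_symbols(gene)
  if (anyDuplicated(gene)) {
    stop("signed_scores requires unique gene symbols", call. = FALSE)
  }
  stopifnot(all(is.finite(sign1)))
  structure(
    data.frame(gene = gene, sign1 = as.numeric(sign1),
               stringsAsFactors = FALSE),
    study_id = study_id, n_duplicates_removed = n_duplicates_removed,
    class = c("signed_scores", "data.frame")
  )
}

#' Remap gene symbols through an alias table
#'
#' Replaces outdated symbols with their current (HUGO) names. When two source
#' symbols collapse onto one target, the entry with the larger |sign1| is
#' kept (ties keep the first in input order); the collision count is logged
#' and attached as an attribute.
#'
#' @param scores A `signed_scores` object.
#' @param aliases Either a two-column data frame `(old, current)` or a named
#'   character vector `c(old = "current", ...)`. Symbols are case-normalized
#'   before matching. An empty map is the identity.
#' @return A `signed_scores` object with attribute `n_collisions`.
#' @export
apply_symbol_map <- function(scores, aliases) {
  map <- as_alias_map(aliases)
  if (length(map) == 0L) {
    attr(scores, "n_collisions") <- 0L
    return(scores)
  }
  gene <- scores$gene
  hit <- match(gene, names(map))
  gene[!is.na(hit)] <- unname(map[hit[!is.na(hit)]])
  ord <- order(-abs(scores$sign1))  # stable; ties keep input order
  keep_idx <- ord[!duplicated(gene[ord])]
  n_coll <- length(gene) - length(keep_idx)
  keep_idx <- sort(keep_idx)
  if (n_coll > 0) {
    sp_log("symbol_collisions", study_id = attr(scores, "study_id"),
           n = n_coll)
  }
  out <- signed_scores(gene[keep_idx], scores$sign1[keep_idx],
                       study_id = attr(scores, "study_id") %||% "study",
                       n_duplicates_removed =
                         attr(scores, "n_duplicates_removed") %||% 0L)
  attr(out, "n_collisions") <- n_coll
  out
}

# Normalize the two accepted alias-map representations to a named vector,
# and make the map idempotent: a chain old -> mid -> new resolves to new.
as_alias_map <- function(aliases) {
  if (is.data.frame(aliases)) {
    stopifnot(ncol(aliases) >= 2)
    map <- stats::setNames(norm_symbols(aliases[[2]]),
                           norm_symbols(aliases[[1]]))
  } else if (is.character(aliases)) {
    map <- stats::setNames(norm_symbols(aliases), norm_symbols(names(aliases)))
  } else {
    stop("aliases must be a two-column data frame or a named character vector",
         call. = FALSE)
  }
  map <- map[names(map) != ""]
  # resolve chains so that applying the map twice equals applying it once
  for (i in seq_along(map)) {
    seen <- character(0)
    while (map[[i]] %in% names(map) && !map[[i]] %in% seen &&
           map[[map[[i]]]] != map[[i]]) {
      seen <- c(seen, map[[i]])
      map[[i]] <- map[[map[[i]]]]
    }
  }
  map
}

#' Read a two-column alias map file
#'
#' @param path TSV with two columns (old symbol, current symbol); a header
#'   line is optional and detected by the literal first field `old`.
#' @return Named character vector usable by [apply_symbol_map()].
#' @export
read_alias_map <- function(path) {
  raw <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(raw) > 0 && tolower(raw[1, 1]) %in% c("old", "old_symbol")) {
    raw <- raw[-1, , drop = FALSE]
  }
  as_alias_map(stats::setNames(raw[[2]], raw[[1]]))
}

#' Write / read the two-column signed-score exchange format
#'
#' The exchange format mirrors the field's two-column convention: a header
#' line `Gene.symbol<TAB>sign1` followed by one gene per line, scores
#' formatted to 6 significant digits. `read_signed_scores(write_signed_scores(x))`
#' equals `x` up to that formatting precision.
#'
#' @param scores A `signed_scores` object.
#' @param path Output (input) file path.
#' @return `write_signed_scores` returns `path` invisibly;
#'   `read_signed_scores` returns a `signed_scores` object.
#' @export
write_signed_scores <- function(scores, path) {
  lines <- c("Gene.symbol\tsign1",
             if (nrow(scores) > 0)
               paste0(scores$gene, "\t", formatC(scores$sign1, digits = 6,
                                                 format = "g")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_signed_scores
#' @param study_id Label attached on read; defaults to the file name.
#' @export
read_signed_scores <- function(path, study_id = NULL) {
  lines <- readLines(path)
  if (length(lines) == 0L || lines[[1]] != "Gene.symbol\tsign1") {
    stop("Not a signed-score file (missing 'Gene.symbol\\tsign1' header): ",
         path, call. = FALSE)
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    return(signed_scores(character(0), numeric(0),
                         study_id = study_id %||%
                           tools::file_path_sans_ext(basename(path))))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2L)) {
    stop("Malformed line ", which(nf != 2L)[1] + 1L, " in ", path,
         call. = FALSE)
  }
  val <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(val)) {
    stop("Non-numeric sign1 on line ", which(is.na(val))[1] + 1L, " in ",
         path, call. = FALSE)
  }
  signed_scores(vapply(parts, `[[`, "", 1L), val,
                study_id = study_id %||%
                  tools::file_path_sans_ext(basename(path)))
}
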