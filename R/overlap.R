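#' Top directional gene lists of a signature
#'
#' First `n` genes of the up- and down-rankings of a signed signature. For a
#' `signed_scores` table the ranking is by sign1; for a `portrait` it is the
#' portrait order (|aggregate score| descending) restricted to each sign.
#' Lists shorter than `n` are returned as-is (no padding) and logged.
#'
#' @param signature A `signed_scores` or `portrait` object.
#' @param n Top-list size per direction (default 1000).
#' @return List with character vectors `up` and `down` (disjoint).
#' @export
top_lists <- function(signature, n = 1000L) {
  stopifnot(n >= 1)
  dl <- directional_order(signature)
  if (length(dl$up) < n || length(dl$down) < n) {
    sp_log("short_top_list", up = length(dl$up), down = length(dl$down),
           n = n)
  }
  list(up = utils::head(dl$up, n), down = utils::head(dl$down, n))
}

# Full directional orderings for either signature representation.
directional_order <- function(signature) {
  if (inherits(signature, "portrait")) {
    list(up = signature$gene[signature$aggregate_score > 0],
         down = signature$gene[signature$aggregate_score < 0])
  } else {
    rank_directional(signature)
  }
}

# Signed per-gene score vector (named), most-up-first ordering for RRHO.
signature_scores <- function(signature) {
  if (inherits(signature, "portrait")) {
    stats::setNames(signature$aggregate_score, signature$gene)
  } else {
    stats::setNames(signature$sign1, signature$gene)
  }
}

#' Hypergeometric over-representation of two gene lists
#'
#' Upper-tail hypergeometric probability `P(X >= k)` of observing `k` common
#' genes between lists of sizes `n1` and `n2` drawn from a universe of size
#' `N`, with `nlp = -log10(max(p, p_floor))`. Genes outside the universe are
#' dropped with a warning.
#'
#' @param list1,list2 Character vectors of gene symbols.
#' @param universe Character vector: the genes jointly measured.
#' @param p_floor Floor applied before the log so reported "p = 0" overlaps
#'   stay finite (default 1e-320).
#' @return An `overlap_result` list: `k`, `n1`, `n2`, `N`, `p`, `nlp`,
#'   `common` (the shared genes).
#' @export
hypergeom_overlap <- function(list1, list2, universe, p_floor = 1e-320) {
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  universe <- unique(universe)
  l1 <- unique(list1); l2 <- unique(list2)
  out1 <- setdiff(l1, universe); out2 <- setdiff(l2, universe)
  if (length(out1) + length(out2) > 0) {
    warning(length(out1) + length(out2),
            " list gene(s) outside the universe dropped", call. = FALSE)
    l1 <- intersect(l1, universe); l2 <- intersect(l2, universe)
  }
  common <- intersect(l1, l2)
  k <- length(common); n1 <- length(l1); n2 <- length(l2)
  N <- length(universe)
  p <- stats::phyper(k - 1, n1, N - n1, n2, lower.tail = FALSE)
  structure(list(k = k, n1 = n1, n2 = n2, N = N,
                 p = p, nlp = neg_log10(p, p_floor), common = common),
            class = "overlap_result")
}

#' Directional quadrant analysis of two signed signatures
#'
#' Compares the top `n` up- and down-regulated genes of two signatures over
#' their shared-gene universe, producing the four quadrant counts:
#' A = up in both, B = up in 1 / down in 2, C = down in 1 / up in 2,
#' D = down in both, with upper-tail hypergeometric probabilities and their
#' −log10 transforms. Both signatures are restricted to the shared universe
#' before the top lists are taken, so every list is a subset of the universe.
#'
#' @param sig1,sig2 `signed_scores` or `portrait` objects.
#' @param n Top-list size per direction (default 1000).
#' @param universe Optional explicit universe; default is the intersection
#'   of the genes measured in both signatures.
#' @param compat_threshold Shared-gene count the pair must exceed to be
#'   considered compatible (default 5000, the dataset filter used for real
#'   screens); failing pairs are flagged, not refused.
#' @param p_floor Floor before −log10 (default 1e-320).
#' @return A `quadrant_result` list with counts `A`–`D`, probabilities
#'   `pA`–`pD`, transforms `nlpA`–`nlpD`, `universe_size`, `list_sizes`,
#'   the four intersections (`genes_A` ... `genes_D`) and
#'   `compatible` (logical flag).
#' @export
quadrant_analysis <- function(sig1, sig2, n = 1000L, universe = NULL,
                              compat_threshold = 5000L, p_floor = 1e-320) {
  g1 <- signature_scores(sig1); g2 <- signature_scores(sig2)
  shared <- intersect(names(g1), names(g2))
  if (!is.null(universe)) shared <- intersect(shared, unique(universe))
  if (length(shared) == 0L) stop("signatures share no genes", call. = FALSE)
  compatible <- length(shared) > compat_threshold
  if (!compatible) {
    sp_log("compatibility_flag", shared = length(shared),
           threshold = compat_threshold)
  }
  t1 <- top_lists(restrict_signature(sig1, shared), n)
  t2 <- top_lists(restrict_signature(sig2, shared), n)
  ov <- function(a, b) hypergeom_overlap(a, b, shared, p_floor)
  qA <- ov(t1$up, t2$up); qB <- ov(t1$up, t2$down)
  qC <- ov(t1$down, t2$up); qD <- ov(t1$down, t2$down)
  structure(list(
    A = qA$k, B = qB$k, C = qC$k, D = qD$k,
    pA = qA$p, pB = qB$p, pC = qC$p, pD = qD$p,
    nlpA = qA$nlp, nlpB = qB$nlp, nlpC = qC$nlp, nlpD = qD$nlp,
    genes_A = qA$common, genes_B = qB$common,
    genes_C = qC$common, genes_D = qD$common,
    universe_size = length(shared),
    list_sizes = c(up1 = length(t1$up), down1 = length(t1$down),
                   up2 = length(t2$up), down2 = length(t2$down)),
    compatible = compatible
  ), class = "quadrant_result")
}

# Keep only genes in `keep`, preserving the signature's own ordering/scores.
restrict_signature <- function(signature, keep) {
  if (inherits(signature, "portrait")) {
    out <- signature[signature$gene %in% keep, , drop = FALSE]
    rownames(out) <- NULL
    structure(out, class = c("portrait", "data.frame"))
  } else {
    idx <- signature$gene %in% keep
    signed_scores(signature$gene[idx], signature$sign1[idx],
                  study_id = attr(signature, "study_id") %||% "study")
  }
}

#' Congruence score of a quadrant result
#'
#' `nlpA + nlpD − nlpB − nlpC`: high when two signatures move the same genes
#' in the same direction (e.g. male vs female disease portraits).
#'
#' @param q A `quadrant_result`.
#' @return Signed numeric score.
#' @export
congruence_score <- function(q) {
  q$nlpA + q$nlpD - q$nlpB - q$nlpC
}

#' Treatment (reversal) score of a quadrant result
#'
#' `nlpB + nlpC − nlpA − nlpD`, the negative of [congruence_score()]: the
#' potential therapeutic effects (treatment reverses disease genes, quadrants
#' B and C) summed, minus the potential detrimental effects (treatment pushes
#' genes the same way as disease, quadrants A and D).
#'
#' @param q A `quadrant_result`.
#' @return Signed numeric score; high = good reverser, strongly negative =
#'   signature resembles the disease (potential risk factor).
#' @export
treatment_score <- function(q) {
  -congruence_score(q)
}

#' Disease genes reversed (or reinforced) by a treatment
#'
#' @param disease_sig,treatment_sig `signed_scores` or `portrait` objects.
#' @param n Top-list size per direction (default 1000).
#' @param ... Passed to [quadrant_analysis()].
#' @return List of disjoint gene sets: `up_reversed` (up in disease, down
#'   under treatment; count = quadrant B), `down_reversed` (down in disease,
#'   up under treatment; count = C), and `same_direction` (A and D genes),
#'   plus the underlying `quadrants`.
#' @export
reversed_genes <- function(disease_sig, treatment_sig, n = 1000L, ...) {
  q <- quadrant_analysis(disease_sig, treatment_sig, n = n, ...)
  list(up_reversed = q$genes_B,
       down_reversed = q$genes_C,
       same_direction = union(q$genes_A, q$genes_D),
       quadrants = q)
}

#' Combine the reversed-gene sets of several treatments
#'
#' Union of the reversed genes across treatments scored against the same
#' disease signature — the "theoretical combination" of treatments. The
#' union count automatically satisfies inclusion–exclusion; pairwise
#' intersection sizes are reported so shared reversals (genes both
#' treatments fix) are visible.
#'
#' @param reversal_sets Named list; each element a list with `up_reversed`
#'   and `down_reversed` character vectors (as returned by
#'   [reversed_genes()]).
#' @return List with `combined` (character vector), `n_combined`,
#'   `per_treatment` (sizes), and `pairwise_intersections` (matrix).
#' @export
combine_treatments <- function(reversal_sets) {
  stopifnot(length(reversal_sets) >= 2L)
  sets <- lapply(reversal_sets, function(r)
    union(r$up_reversed, r$down_reversed))
  nm <- names(sets) %||% paste0("treatment", seq_along(sets))
  nm[nm == ""] <- paste0("treatment", which(nm == ""))
  names(sets) <- nm
  combined <- sort(unique(unlist(sets)))
  pw <- outer(seq_along(sets), seq_along(sets),
              Vectorize(function(i, j) length(intersect(sets[[i]], sets[[j]]))))
  dimnames(pw) <- list(nm, nm)
  list(combined = combined,
       n_combined = length(combined),
       per_treatment = vapply(sets, length, integer(1)),
       pairwise_intersections = pw)
}

#' Rank candidate treatments against a disease signature
#'
#' Runs [quadrant_analysis()] for every treatment and orders them by
#' [treatment_score()] descending (ties: more reversed genes first, then
#' dataset id). The compatibility flag (shared genes above threshold) is
#' carried per row; `strict = TRUE` drops incompatible treatments instead,
#' matching a real screen's dataset filter.
#'
#' @param disease A `signed_scores` or `portrait` object.
#' @param treatments Named list of `signed_scores` (or `portrait`) objects.
#' @param n Top-list size per direction (default 1000).
#' @param strict Drop incompatible treatments instead of flagging
#'   (default FALSE).
#' @param ... Passed to [quadrant_analysis()].
#' @return A data frame (class `treatment_ranking`) with one row per
#'   treatment: `dataset_id`, `score`, `A`–`D`, `nlpA`–`nlpD`,
#'   `reversal_total` (B+C), `same_direction_total` (A+D), `compatible`;
#'   sorted best reverser first.
#' @export
rank_treatments <- function(disease, treatments, n = 1000L, strict = FALSE,
                            ...) {
  if (length(treatments) == 0L) {
    out <- data.frame(dataset_id = character(0), score = numeric(0),
                      A = integer(0), B = integer(0), C = integer(0),
                      D = integer(0), nlpA = numeric(0), nlpB = numeric(0),
                      nlpC = numeric(0), nlpD = numeric(0),
                      reversal_total = integer(0),
                      same_direction_total = integer(0),
                      compatible = logical(0), stringsAsFactors = FALSE)
    return(structure(out, class = c("treatment_ranking", "data.frame")))
  }
  ids <- dataset_ids(treatments)
  rows <- lapply(seq_along(treatments), function(i) {
    q <- quadrant_analysis(disease, treatments[[i]], n = n, ...)
    data.frame(dataset_id = ids[[i]], score = treatment_score(q),
               A = q$A, B = q$B, C = q$C, D = q$D,
               nlpA = q$nlpA, nlpB = q$nlpB, nlpC = q$nlpC, nlpD = q$nlpD,
               reversal_total = q$B + q$C,
               same_direction_total = q$A + q$D,
               compatible = q$compatible, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (strict) out <- out[out$compatible, , drop = FALSE]
  out <- out[order(-out$score, -out$reversal_total, out$dataset_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("treatment_ranking", "data.frame"))
}

#' Overlap of an undirected gene list with a signature's top genes
#'
#' Thin wrapper over [hypergeom_overlap()] for, e.g., testing GWAS hit lists
#' against the top portrait genes.
#'
#' @param list_a Character vector (e.g. GWAS genes).
#' @param signature_top Character vector (e.g. top 1000 portrait genes).
#' @param universe Character vector of jointly measured genes.
#' @param ... Passed to [hypergeom_overlap()].
#' @return An `overlap_result` (includes the common genes).
#' @export
gene_list_overlap <- function(list_a, signature_top, universe, ...) {
  hypergeom_overlap(list_a, signature_top, universe, ...)
}
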