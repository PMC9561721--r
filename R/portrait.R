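#' Rank-stratum weight scheme
#'
#' Genes in each study's directional ranking are weighted by the rank stratum
#' they fall in: by default ranks 1–1000 get weight 8, 1001–2000 get 7, and
#' so on down to weight 1 for ranks 7001–8000; ranks beyond the final bound
#' get weight 0. Piecewise-constant, decreasing weights let every study
#' contribute equally through its ranks regardless of its p-value scale.
#'
#' @param bounds Strictly increasing rank cutoffs (default
#'   `seq(1000, 8000, by = 1000)`).
#' @param weights Strictly decreasing positive weights, one per stratum
#'   (default `8:1`).
#' @return A `weight_scheme` object.
#' @export
weight_scheme <- function(bounds = seq(1000L, 8000L, by = 1000L),
                          weights = 8:1) {
  bounds <- as.numeric(bounds); weights <- as.numeric(weights)
  if (length(bounds) != length(weights)) {
    stop("bounds and weights must have equal length", call. = FALSE)
  }
  if (any(diff(bounds) <= 0)) stop("bounds must be strictly increasing",
                                   call. = FALSE)
  if (any(weights <= 0) || any(diff(weights) >= 0)) {
    stop("weights must be positive and strictly decreasing", call. = FALSE)
  }
  structure(list(bounds = bounds, weights = weights),
            class = "weight_scheme")
}

#' Weight of a rank under a scheme
#'
#' @param rank Positive integer rank(s) in a directional gene ranking.
#' @param scheme A [weight_scheme()].
#' @return Nonnegative weight(s); 0 beyond the last bound.
#' @export
#' @examples
#' stratum_weight(c(1, 1500, 9000), weight_scheme())  # 8 7 0
stratum_weight <- function(rank, scheme = weight_scheme()) {
  if (any(rank < 1)) stop("rank must be >= 1", call. = FALSE)
  idx <- findInterval(rank - 1, c(0, scheme$bounds)) # stratum index
  w <- c(scheme$weights, 0)[pmin(idx, length(scheme$weights) + 1L)]
  w
}

#' Directional rankings of a signed-score table
#'
#' Splits a signature into an up-list (sign1 > 0, strongest first, i.e.
#' descending sign1) and a down-list (sign1 < 0, most negative first). Genes
#' with sign1 = 0 appear in neither. Ties in |sign1| break alphabetically so
#' builds are reproducible.
#'
#' @param scores A `signed_scores` object (or any data frame with `gene` and
#'   `sign1` columns).
#' @return List with character vectors `up` and `down`.
#' @export
rank_directional <- function(scores) {
  up_i <- which(scores$sign1 > 0)
  dn_i <- which(scores$sign1 < 0)
  up <- scores$gene[up_i][order(-scores$sign1[up_i], scores$gene[up_i])]
  down <- scores$gene[dn_i][order(scores$sign1[dn_i], scores$gene[dn_i])]
  list(up = up, down = down)
}

#' Build a consensus portrait from many signed-score tables
#'
#' Each dataset votes for a gene with `+stratum_weight(rank in its up-list)`
#' or `-stratum_weight(rank in its down-list)`; the portrait aggregate score
#' is the sum of those votes. Genes must be measured in strictly more than
#' `min_presence_fraction` of the datasets to enter the portrait, and at most
#' `max_per_study` datasets may share a `study_id` in the manifest so no one
#' study dominates. Output is ordered from most to least dysregulated:
#' |aggregate| descending, ties by |mean sign1| descending, then
#' alphabetically; genes whose votes cancel to 0 have undefined direction and
#' sort last.
#'
#' @param tables List of `signed_scores` objects (names or `study_id`
#'   attributes identify datasets).
#' @param manifest Optional data frame with columns `dataset_id`, `study_id`
#'   (and optionally `sex`, `region`). When supplied, every table must be
#'   covered and no `study_id` may own more than `max_per_study` datasets.
#' @param scheme A [weight_scheme()].
#' @param min_presence_fraction Presence filter; a gene is kept iff present
#'   in strictly more than this fraction of datasets (default 2/3).
#' @param max_per_study Per-study dataset cap (default 2; `Inf` disables,
#'   as [build_composite()] does).
#' @param min_tables Minimum number of input tables (default 2;
#'   [build_composite()] relaxes this to 1 — a single-dataset composite is
#'   just that dataset's directional ranking within the weighted strata).
#' @return A `portrait`: data frame with columns `gene`, `aggregate_score`,
#'   `n_studies_present`, `mean_sign1`, `rank`; attributes `n_datasets`,
#'   `n_filtered` (genes removed by the presence filter).
#' @export
build_portrait <- function(tables, manifest = NULL,
                           scheme = weight_scheme(),
                           min_presence_fraction = 2 / 3,
                           max_per_study = 2L, min_tables = 2L) {
  if (length(tables) < min_tables) {
    stop("need at least ", min_tables, " table(s)", call. = FALSE)
  }
  ids <- dataset_ids(tables)
  if (!is.null(manifest) && is.finite(max_per_study)) {
    miss <- setdiff(ids, manifest$dataset_id)
    if (length(miss) > 0) {
      stop("manifest does not cover dataset(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    m <- manifest[manifest$dataset_id %in% ids, , drop = FALSE]
    per <- table(m$study_id)
    if (any(per > max_per_study)) {
      stop("more than ", max_per_study, " datasets for study_id(s): ",
           paste(names(per)[per > max_per_study], collapse = ", "),
           call. = FALSE)
    }
  }
  n_data <- length(tables)

  genes <- sort(unique(unlist(lapply(tables, `[[`, "gene"))))
  score <- stats::setNames(numeric(length(genes)), genes)
  presence <- stats::setNames(integer(length(genes)), genes)
  sign1_sum <- stats::setNames(numeric(length(genes)), genes)

  for (tab in tables) {
    presence[tab$gene] <- presence[tab$gene] + 1L
    sign1_sum[tab$gene] <- sign1_sum[tab$gene] + tab$sign1
    dl <- rank_directional(tab)
    if (length(dl$up) > 0) {
      w <- stratum_weight(seq_along(dl$up), scheme)
      score[dl$up] <- score[dl$up] + w
    }
    if (length(dl$down) > 0) {
      w <- stratum_weight(seq_along(dl$down), scheme)
      score[dl$down] <- score[dl$down] - w
    }
  }

  keep <- presence > min_presence_fraction * n_data  # strictly more than
  n_filtered <- sum(!keep)
  if (!any(keep)) {
    warning("presence filter removed every gene: empty portrait",
            call. = FALSE)
  }
  g <- genes[keep]
  mean_sign1 <- sign1_sum[g] / presence[g]
  out <- data.frame(gene = g,
                    aggregate_score = unname(score[g]),
                    n_studies_present = unname(presence[g]),
                    mean_sign1 = unname(mean_sign1),
                    stringsAsFactors = FALSE)
  ord <- order(-abs(out$aggregate_score), -abs(out$mean_sign1), out$gene)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, n_datasets = n_data, n_filtered = n_filtered,
            class = c("portrait", "data.frame"))
}

#' Build a treatment composite
#'
#' Identical aggregation to [build_portrait()] but without the per-study
#' dataset cap (composites pool many datasets of the same treatment, e.g.
#' 11 exercise datasets, so the cap does not apply unless a manifest with a
#' cap is wanted).
#'
#' @inheritParams build_portrait
#' @return A `portrait`.
#' @export
build_composite <- function(tables, scheme = weight_scheme(),
                            min_presence_fraction = 2 / 3,
                            manifest = NULL) {
  build_portrait(tables, manifest = manifest, scheme = scheme,
                 min_presence_fraction = min_presence_fraction,
                 max_per_study = Inf, min_tables = 1L)
}

#' Sign-reversed portrait
#'
#' Negates every aggregate score and mean sign1 without reordering, turning
#' a disease portrait into its ideal "perfect treatment" signature (used,
#' e.g., before embedding treatments so better reversers plot closer).
#'
#' @param p A `portrait`.
#' @return A `portrait` with all signs flipped; `reverse_portrait` is an
#'   involution.
#' @export
reverse_portrait <- function(p) {
  p$aggregate_score <- -p$aggregate_score
  p$mean_sign1 <- -p$mean_sign1
  p
}

#' Write / read a portrait TSV
#'
#' @param p A `portrait`.
#' @param path File path.
#' @return `write_portrait` returns `path` invisibly; `read_portrait`
#'   returns a `portrait`.
#' @export
write_portrait <- function(p, path) {
  utils::write.table(as.data.frame(p), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_portrait
#' @export
read_portrait <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("gene", "aggregate_score", "n_studies_present", "mean_sign1",
            "rank")
  if (!all(need %in% names(out))) {
    stop("not a portrait file (columns ", paste(need, collapse = ", "),
         " required): ", path, call. = FALSE)
  }
  structure(out, class = c("portrait", "data.frame"))
}

# dataset ids for a list of signed_scores: names if set, else study_id attrs
dataset_ids <- function(tables) {
  ids <- names(tables)
  from_attr <- vapply(tables, function(t) attr(t, "study_id") %||% NA_character_,
                      character(1))
  if (is.null(ids)) ids <- from_attr
  ids[is.na(ids) | ids == ""] <- from_attr[is.na(ids) | ids == ""]
  ids[is.na(ids) | ids == ""] <- paste0("dataset", which(is.na(ids) | ids == ""))
  ids
}
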