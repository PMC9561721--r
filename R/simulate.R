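#' Simulation configuration for synthetic multi-study collections
#'
#' Describes the statistical world the portrait machinery assumes: a set of
#' genes with a consistent planted directional signal shared by every study,
#' embedded in study-specific null noise. Null genes get uniform p-values
#' (a valid null) and random direction signs; planted genes get log-uniform
#' p-values over `planted_p_range`, which lands them inside each study's top
#' rank stratum, with a consistent sign across studies. Per-study
#' missingness removes a fraction of the null background independently in
#' each study (planted genes are always measured — they are the consistent
#' cross-study signal being planted).
#'
#' @param n_genes Total genes (default 15000, roughly protein-coding scale).
#' @param n_studies Number of disease studies (default 6).
#' @param n_planted_up,n_planted_down Planted consistently up/down genes
#'   (defaults 50 each).
#' @param planted_rank_ceiling Planted genes must fit within this top rank
#'   in every study (default 1000, the first stratum); configuration error
#'   if the planted count exceeds it.
#' @param planted_p_range Range of the log-uniform planted p-value
#'   distribution (default `c(1e-12, 1e-4)`).
#' @param missing_fraction Per-study fraction of null genes absent
#'   (default 0.1, typical of cross-platform GEO exports).
#' @param reversal_fraction Default fraction of planted genes a generated
#'   treatment reverses (default 0.4).
#' @param seed Integer seed; fixed seed gives identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 15000L, n_studies = 6L,
                       n_planted_up = 50L, n_planted_down = 50L,
                       planted_rank_ceiling = 1000L,
                       planted_p_range = c(1e-12, 1e-4),
                       missing_fraction = 0.1,
                       reversal_fraction = 0.4,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_studies = as.integer(n_studies),
              n_planted_up = as.integer(n_planted_up),
              n_planted_down = as.integer(n_planted_down),
              planted_rank_ceiling = as.integer(planted_rank_ceiling),
              planted_p_range = as.numeric(planted_p_range),
              missing_fraction = missing_fraction,
              reversal_fraction = reversal_fraction,
              seed = as.integer(seed))
  with(cfg, {
    if (n_planted_up + n_planted_down >= n_genes) {
      stop("planted genes must be fewer than n_genes", call. = FALSE)
    }
    if (max(n_planted_up, n_planted_down) > planted_rank_ceiling) {
      stop("planted count per direction exceeds planted_rank_ceiling",
           call. = FALSE)
    }
    if (missing_fraction < 0 || missing_fraction > 1 ||
        reversal_fraction < 0 || reversal_fraction > 1) {
      stop("fractions must lie in [0, 1]", call. = FALSE)
    }
  })
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic multi-study DE collection with known ground truth
#'
#' @param config A [sim_config()].
#' @return List with `tables` (named list of `deg_table`, one per study) and
#'   `truth` (list with `planted_up`, `planted_down` gene sets).
#' @export
#' @examples
#' sim <- generate_study_collection(sim_config(n_genes = 500, n_studies = 3,
#'                                             n_planted_up = 5,
#'                                             n_planted_down = 5, seed = 7))
#' names(sim$tables)
generate_study_collection <- function(config = sim_config()) {
  set.seed(config$seed)
  genes <- sprintf("G%06d", seq_len(config$n_genes))
  planted <- sample(genes, config$n_planted_up + config$n_planted_down)
  planted_up <- sort(utils::head(planted, config$n_planted_up))
  planted_down <- sort(utils::tail(planted, config$n_planted_down))
  is_planted <- genes %in% planted
  lo <- log10(config$planted_p_range[1]); hi <- log10(config$planted_p_range[2])

  tables <- lapply(seq_len(config$n_studies), function(s) {
    p <- stats::runif(config$n_genes)
    lfc <- stats::rnorm(config$n_genes)
    p[is_planted] <- 10^stats::runif(sum(is_planted), lo, hi)
    up_i <- genes %in% planted_up
    dn_i <- genes %in% planted_down
    lfc[up_i] <- abs(stats::rnorm(sum(up_i), mean = 1, sd = 0.3))
    lfc[dn_i] <- -abs(stats::rnorm(sum(dn_i), mean = 1, sd = 0.3))
    present <- is_planted |
      stats::runif(config$n_genes) >= config$missing_fraction
    deg_table(genes[present], p[present], lfc[present],
              study_id = sprintf("SIM%03d", s))
  })
  names(tables) <- vapply(tables, attr, "", "study_id")
  list(tables = tables,
       truth = list(planted_up = planted_up, planted_down = planted_down))
}

#' Generate a synthetic treatment signature with a known reversal fraction
#'
#' Flips the sign of `round(reversal_fraction * n_planted)` planted disease
#' genes (drawn evenly from the up and down sets) and gives them small
#' p-values; every other gene is null (uniform p, random sign).
#' `reversal_fraction = 0` yields a null treatment; `1` a full planted-set
#' reverser.
#'
#' @param config A [sim_config()] (gene universe, p distributions,
#'   missingness).
#' @param disease_truth The `truth` element from
#'   [generate_study_collection()].
#' @param reversal_fraction Fraction of planted genes reversed; defaults to
#'   `config$reversal_fraction`.
#' @param dataset_id Label for the treatment table.
#' @param seed Seed for this treatment's draws (defaults to
#'   `config$seed + 1`).
#' @return List with `table` (a `deg_table`) and `reversed` (the gene set
#'   whose signs were flipped).
#' @export
generate_treatment <- function(config, disease_truth,
                               reversal_fraction = config$reversal_fraction,
                               dataset_id = "treatment",
                               seed = config$seed + 1L) {
  stopifnot(reversal_fraction >= 0, reversal_fraction <= 1)
  set.seed(seed)
  genes <- sprintf("G%06d", seq_len(config$n_genes))
  p <- stats::runif(config$n_genes)
  lfc <- stats::rnorm(config$n_genes)

  up <- disease_truth$planted_up; dn <- disease_truth$planted_down
  n_flip <- round(reversal_fraction * (length(up) + length(dn)))
  n_up <- min(length(up), round(n_flip * length(up) / (length(up) + length(dn))))
  n_dn <- min(length(dn), n_flip - n_up)
  flip <- c(sample(up, n_up), sample(dn, n_dn))
  lo <- log10(config$planted_p_range[1]); hi <- log10(config$planted_p_range[2])
  if (length(flip) > 0) {
    idx <- match(flip, genes)
    p[idx] <- 10^stats::runif(length(idx), lo, hi)
    # opposite sign to the disease direction
    lfc[idx] <- ifelse(flip %in% up, -1, 1) *
      abs(stats::rnorm(length(idx), mean = 1, sd = 0.3))
  }
  keep_planted <- genes %in% c(up, dn)
  present <- keep_planted |
    stats::runif(config$n_genes) >= config$missing_fraction
  list(table = deg_table(genes[present], p[present], lfc[present],
                         study_id = dataset_id),
       reversed = sort(flip))
}

#' Write a simulated collection to disk as GEO2R-style TSVs plus truth JSON
#'
#' @param sim Output of [generate_study_collection()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly; files are `<study_id>.tsv` with columns
#'   `Gene.symbol`, `P.Value`, `logFC`, plus `truth.json`.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tab in sim$tables) {
    out <- data.frame(Gene.symbol = tab$gene, P.Value = tab$p_value,
                      logFC = tab$direction, check.names = FALSE)
    utils::write.table(out, file.path(dir, paste0(attr(tab, "study_id"),
                                                  ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"))
  invisible(dir)
}
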