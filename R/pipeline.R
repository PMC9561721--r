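#' Run the full portrait / treatment-scoring pipeline
#'
#' Orchestrates ingest -> signed scores -> portrait -> treatment ranking ->
#' reversed-gene sets -> RRHO for one configuration, writing deterministic
#' TSV outputs and a machine-readable run manifest. Re-running an identical
#' configuration reproduces byte-identical TSVs.
#'
#' @param config Either a YAML file path or a named list with keys:
#'   \describe{
#'     \item{datasets}{path to a TSV manifest with columns `dataset_id`,
#'       `study_id`, `path` (per-study DE tables; paths relative to the
#'       manifest), optional `sex`, `region`.}
#'     \item{treatments}{optional TSV manifest with `dataset_id`, `path`.}
#'     \item{out_dir}{output directory.}
#'     \item{format}{optional list for [read_de_table()] (`gene_col`,
#'       `pval_col`, `lfc_col`, `delimiter`).}
#'     \item{aliases}{optional path to a two-column symbol alias TSV.}
#'     \item{n}{top-list size, default 1000.}
#'     \item{stratum_bounds,stratum_weights}{weight scheme, defaults
#'       1000..8000 / 8..1.}
#'     \item{min_presence_fraction}{default 2/3.}
#'     \item{max_per_study}{default 2.}
#'     \item{p_floor}{overlap floor, default 1e-320.}
#'     \item{sign1_p_floor}{default 1e-300.}
#'     \item{rrho_step}{default 100 (set 0 to skip RRHO).}
#'     \item{compat_threshold}{default 5000.}
#'     \item{strict}{drop incompatible treatments, default FALSE.}
#'   }
#' @return Invisibly, a list with `portrait`, `ranking`, `reversed`,
#'   `manifest` (also written to `out_dir/run_manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(n = 1000L, stratum_bounds = seq(1000L, 8000L, 1000L),
                   stratum_weights = 8:1, min_presence_fraction = 2 / 3,
                   max_per_study = 2L, p_floor = 1e-320,
                   sign1_p_floor = 1e-300, rrho_step = 100L,
                   compat_threshold = 5000L, strict = FALSE,
                   format = list(), aliases = NULL, treatments = NULL)
  config <- utils::modifyList(defaults, config)
  if (is.null(config$datasets) || is.null(config$out_dir)) {
    stop("config must name 'datasets' (manifest TSV) and 'out_dir'",
         call. = FALSE)
  }
  scheme <- weight_scheme(config$stratum_bounds, config$stratum_weights)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  aliases <- if (!is.null(config$aliases)) read_alias_map(config$aliases)

  ingest <- function(manifest_path, stage) {
    if (!file.exists(manifest_path)) {
      stop("[", stage, "] manifest not found: ", manifest_path,
           call. = FALSE)
    }
    man <- utils::read.table(manifest_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    tabs <- list(); counts <- list()
    for (i in seq_len(nrow(man))) {
      path <- man$path[i]
      if (!file.exists(path)) {
        path2 <- file.path(dirname(manifest_path), man$path[i])
        if (!file.exists(path2)) {
          stop("[", stage, "] dataset file not found: ", man$path[i],
               call. = FALSE)
        }
        path <- path2
      }
      deg <- tryCatch(
        read_de_table(path, config$format, study_id = man$dataset_id[i]),
        error = function(e) stop("[", stage, "] ", conditionMessage(e),
                                 call. = FALSE))
      sc <- to_signed_scores(deg, p_floor = config$sign1_p_floor)
      if (!is.null(aliases)) sc <- apply_symbol_map(sc, aliases)
      tabs[[man$dataset_id[i]]] <- sc
      counts[[man$dataset_id[i]]] <-
        list(n_genes = nrow(sc), n_dropped = attr(deg, "n_dropped"),
             n_duplicates_removed = attr(sc, "n_duplicates_removed"),
             n_collisions = attr(sc, "n_collisions") %||% 0L)
    }
    list(manifest = man, tables = tabs, counts = counts)
  }

  dz <- ingest(config$datasets, "ingest")
  prt <- tryCatch(
    build_portrait(dz$tables, manifest = dz$manifest, scheme = scheme,
                   min_presence_fraction = config$min_presence_fraction,
                   max_per_study = config$max_per_study),
    error = function(e) stop("[portrait] ", conditionMessage(e),
                             call. = FALSE))
  write_portrait(prt, file.path(config$out_dir, "portrait.tsv"))

  ranking <- NULL; reversed <- NULL
  if (!is.null(config$treatments)) {
    tr <- ingest(config$treatments, "score")
    ranking <- rank_treatments(prt, tr$tables, n = config$n,
                               strict = config$strict,
                               compat_threshold = config$compat_threshold,
                               p_floor = config$p_floor)
    utils::write.table(as.data.frame(ranking),
                       file.path(config$out_dir, "treatments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(ranking) > 0) {
      top_id <- ranking$dataset_id[1]
      reversed <- reversed_genes(prt, tr$tables[[top_id]], n = config$n,
                                 compat_threshold = config$compat_threshold,
                                 p_floor = config$p_floor)
      writeLines(sort(reversed$up_reversed),
                 file.path(config$out_dir, "top_treatment_up_reversed.txt"))
      writeLines(sort(reversed$down_reversed),
                 file.path(config$out_dir, "top_treatment_down_reversed.txt"))
      if (config$rrho_step > 0) {
        map <- rrho_grid(prt, tr$tables[[top_id]], step = config$rrho_step,
                         p_floor = config$p_floor)
        write_rrho(map, file.path(config$out_dir, "rrho_top_treatment.tsv"))
        render_rrho(map, file.path(config$out_dir, "rrho_top_treatment.png"))
      }
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("sigportrait")),
    parameters = config[c("n", "stratum_bounds", "stratum_weights",
                          "min_presence_fraction", "max_per_study",
                          "p_floor", "sign1_p_floor", "rrho_step",
                          "compat_threshold", "strict")],
    datasets = dz$counts,
    treatments = if (!is.null(config$treatments))
      lapply(ranking$dataset_id, function(i) i),
    portrait = list(n_genes = nrow(prt),
                    n_filtered_by_presence = attr(prt, "n_filtered"),
                    n_datasets = attr(prt, "n_datasets"))
  )
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(portrait = prt, ranking = ranking, reversed = reversed,
                 manifest = manifest))
}

#' Command-line interface
#'
#' Subcommand-style CLI mirroring the analysis stages. Intended to be called
#' from the launcher script installed at
#' `system.file("cli", "sigportrait.R", package = "sigportrait")`, or
#' programmatically with an argument vector.
#'
#' Subcommands:
#' \describe{
#'   \item{simulate}{`--out DIR [--seed N] [--n-genes N] [--n-studies N]
#'     [--planted-up N] [--planted-down N] [--missing-fraction X]` — write a
#'     synthetic study collection (GEO2R-style TSVs + truth.json + a dataset
#'     manifest).}
#'   \item{ingest}{`--in DE_TSV --out SIGN1_TSV [--gene-col C] [--pval-col C]
#'     [--lfc-col C]` — DE table to two-column signed-score file.}
#'   \item{portrait}{`--manifest TSV --out TSV [--presence X]` — build a
#'     portrait from a dataset manifest.}
#'   \item{composite}{same flags as `portrait` but without the per-study
#'     dataset cap (treatment composites).}
#'   \item{combine}{`--lists F1,F2,... --out JSON` — union of reversed-gene
#'     list files with pairwise intersection counts.}
#'   \item{score}{`--portrait TSV --treatments MANIFEST --out TSV [--n N]` —
#'     rank treatments against a portrait.}
#'   \item{rrho}{`--x SIGN1_TSV --y SIGN1_TSV --out TSV [--png PNG]
#'     [--step N]` — RRHO grid between two signed-score files.}
#'   \item{run}{`--config YAML` — full pipeline via [run_pipeline()].}
#' }
#'
#' @param args Character vector of command-line arguments (defaults to the
#'   process arguments).
#' @return Exit status, invisibly (0 on success); errors raise conditions —
#'   the launcher script converts them to nonzero exit codes with a
#'   stage-tagged message.
#' @export
sigportrait_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    stop("usage: sigportrait <simulate|ingest|portrait|score|rrho|run> ...",
         call. = FALSE)
  }
  cmd <- args[[1]]
  opt <- parse_cli_flags(args[-1])
  need <- function(key) {
    if (is.null(opt[[key]])) {
      stop("[", cmd, "] missing required flag --", key, call. = FALSE)
    }
    opt[[key]]
  }
  switch(
    cmd,
    simulate = {
      cfg <- sim_config(
        n_genes = as.integer(opt[["n-genes"]] %||% 15000L),
        n_studies = as.integer(opt[["n-studies"]] %||% 6L),
        n_planted_up = as.integer(opt[["planted-up"]] %||% 50L),
        n_planted_down = as.integer(opt[["planted-down"]] %||% 50L),
        missing_fraction = as.numeric(opt[["missing-fraction"]] %||% 0.1),
        seed = as.integer(opt[["seed"]] %||% 1L))
      sim <- generate_study_collection(cfg)
      dir <- need("out")
      write_simulation(sim, dir)
      man <- data.frame(dataset_id = names(sim$tables),
                        study_id = names(sim$tables),
                        path = paste0(names(sim$tables), ".tsv"))
      utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    },
    ingest = {
      deg <- read_de_table(need("in"), list(
        gene_col = opt[["gene-col"]] %||% "Gene.symbol",
        pval_col = opt[["pval-col"]] %||% "P.Value",
        lfc_col = opt[["lfc-col"]] %||% "logFC"))
      write_signed_scores(to_signed_scores(deg), need("out"))
    },
    portrait = ,
    composite = {
      man <- utils::read.table(need("manifest"), header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
      base <- dirname(need("manifest"))
      tabs <- lapply(seq_len(nrow(man)), function(i) {
        p <- if (file.exists(man$path[i])) man$path[i] else
          file.path(base, man$path[i])
        to_signed_scores(read_de_table(p, study_id = man$dataset_id[i]))
      })
      names(tabs) <- man$dataset_id
      frac <- as.numeric(opt[["presence"]] %||% (2 / 3))
      prt <- if (cmd == "composite") {
        build_composite(tabs, min_presence_fraction = frac)
      } else {
        build_portrait(tabs, manifest = man, min_presence_fraction = frac)
      }
      write_portrait(prt, need("out"))
    },
    combine = {
      paths <- strsplit(need("lists"), ",", fixed = TRUE)[[1]]
      if (length(paths) < 2L) {
        stop("[combine] need at least two list files", call. = FALSE)
      }
      sets <- lapply(paths, function(p)
        list(up_reversed = norm_symbols(readLines(p)),
             down_reversed = character(0)))
      names(sets) <- tools::file_path_sans_ext(basename(paths))
      comb <- combine_treatments(sets)
      jsonlite::write_json(
        list(n_combined = comb$n_combined,
             per_treatment = as.list(comb$per_treatment),
             pairwise_intersections = comb$pairwise_intersections,
             combined = comb$combined),
        need("out"), auto_unbox = TRUE, digits = NA)
    },
    score = {
      prt <- read_portrait(need("portrait"))
      man <- utils::read.table(need("treatments"), header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
      base <- dirname(need("treatments"))
      tabs <- lapply(seq_len(nrow(man)), function(i) {
        p <- if (file.exists(man$path[i])) man$path[i] else
          file.path(base, man$path[i])
        to_signed_scores(read_de_table(p, study_id = man$dataset_id[i]))
      })
      names(tabs) <- man$dataset_id
      rk <- rank_treatments(prt, tabs,
                            n = as.integer(opt[["n"]] %||% 1000L))
      utils::write.table(as.data.frame(rk), need("out"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    },
    rrho = {
      map <- rrho_grid(read_signed_scores(need("x")),
                       read_signed_scores(need("y")),
                       step = as.integer(opt[["step"]] %||% 100L))
      write_rrho(map, need("out"))
      if (!is.null(opt[["png"]])) render_rrho(map, opt[["png"]])
    },
    run = {
      run_pipeline(need("config"))
    },
    stop("unknown subcommand '", cmd, "'", call. = FALSE)
  )
  invisible(0L)
}

# --key value flag parser (no positional arguments after the subcommand)
parse_cli_flags <- function(args) {
  opt <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[[i]], "--")) {
      stop("unexpected argument '", args[[i]], "'", call. = FALSE)
    }
    key <- substring(args[[i]], 3)
    if (i == length(args) || startsWith(args[[i + 1L]], "--")) {
      opt[[key]] <- TRUE
      i <- i + 1L
    } else {
      opt[[key]] <- args[[i + 1L]]
      i <- i + 2L
    }
  }
  opt
}
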