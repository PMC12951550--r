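# End-to-end orchestration: target discovery (network -> filtration ->
# sheaf spectra -> perturbation ranking) and drug repurposing (activity ->
# ensemble -> binder calls -> CNS screen), plus a small CLI.

#' Run configuration
#'
#' Collects every tunable of the two pipelines with the published
#' defaults: confidence thresholds 250/400/550/700, top 200 up-regulated
#' DEGs, top-k 25 per scale, clique dimension 2, strict/relaxed binding
#' cutoffs -9.2 / -8.5 kcal/mol, BBB > 0.70 and P-gp < 0.50.
#'
#' @param deg_path,edge_path target-discovery inputs (DEG CSV, edge TSV).
#' @param activity_path,candidate_path,admet_path repurposing inputs.
#' @param out_dir where reports are written.
#' @param thresholds confidence thresholds (strictly increasing).
#' @param top_n_degs DEG selection size.
#' @param p_max DEG p-value gate.
#' @param top_k per-scale prefix for the intersection.
#' @param max_dim maximum clique dimension.
#' @param q_floor,r_floor sheaf floors (labels / edge lengths).
#' @param delta_g_max binder free-energy cutoff in kcal/mol.
#' @param bbb_min,pgp_max ADMET policy bounds.
#' @param seed integer seed for every stochastic step.
#' @param grid hyperparameter grid forwarded to
#'   [train_affinity_ensemble()].
#' @param deg_dialect,edge_columns column-name mappings for the readers.
#' @return a validated `run_config` list.
#' @export
run_config <- function(deg_path = NULL, edge_path = NULL,
                       activity_path = NULL, candidate_path = NULL,
                       admet_path = NULL, out_dir = tempdir(),
                       thresholds = c(250L, 400L, 550L, 700L),
                       top_n_degs = 200L, p_max = 0.05, top_k = 25L,
                       max_dim = 2L, q_floor = 1e-6, r_floor = 1e-3,
                       delta_g_max = -9.2, bbb_min = 0.70, pgp_max = 0.50,
                       seed = 1L, grid = default_grid(),
                       deg_dialect = list(gene = "gene", log2fc = "log2fc",
                                          pvalue = "pvalue"),
                       edge_columns = list(gene_a = "gene_a",
                                           gene_b = "gene_b",
                                           score = "combined_score")) {
  stopifnot(top_n_degs >= 1L, top_k >= 1L, max_dim %in% 1:3,
            !is.unsorted(thresholds, strictly = TRUE))
  structure(as.list(environment()), class = "run_config")
}

config_manifest <- function(config, inputs, extra = list()) {
  sums <- vapply(inputs, function(p) unname(tools::md5sum(p)), character(1))
  cfg <- config[!vapply(config, is.null, logical(1))]
  c(list(package = "pslscreen",
         version = as.character(utils::packageVersion("pslscreen")),
         config = cfg, input_md5 = as.list(sums)),
    extra)
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

#' Run the target-discovery pipeline
#'
#' DEG selection, labeled network assembly, clique-complex filtration,
#' sheaf-Laplacian perturbation scoring and top-k intersection. Writes
#' `scores.csv` (gene, scale, distance, rank, in_final_set),
#' `final_genes.txt` and `discovery_manifest.json` into `config$out_dir`.
#' Outputs contain no timestamps, so a rerun with the same config is
#' byte-identical.
#'
#' @param config a [run_config()] with `deg_path` and `edge_path` set.
#' @return the `ranking_result`, invisibly.
#' @export
run_target_discovery <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  degs <- stage("network_io", {
    all_degs <- read_deg_table(config$deg_path, config$deg_dialect)
    select_top_upregulated(all_degs, n = config$top_n_degs,
                           p_max = config$p_max)
  })
  network <- stage("network_io", {
    edges <- read_interaction_edges(config$edge_path, config$edge_columns)
    build_labeled_network(degs, edges, q_floor = config$q_floor)
  })
  filtration <- stage("clique_filtration",
    build_confidence_filtration(network, config$thresholds, config$max_dim))
  sheaf <- stage("sheaf_spectra",
    default_sheaf(network, r_floor = config$r_floor))
  scores <- stage("perturbation_ranking",
    score_genes(network, filtration, sheaf))
  result <- stage("perturbation_ranking",
    rank_and_intersect(scores, top_k = config$top_k))

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(result$table, file.path(config$out_dir, "scores.csv"))
  writeLines(result$intersected,
             file.path(config$out_dir, "final_genes.txt"))
  write_manifest(
    config_manifest(config, c(config$deg_path, config$edge_path),
                    list(n_genes = length(network$genes),
                         n_edges = nrow(network$edges),
                         intersected = result$intersected)),
    file.path(config$out_dir, "discovery_manifest.json"))
  invisible(result)
}

#' Run the drug-repurposing pipeline
#'
#' Cleans the activity table, trains the dual gradient-boosted ensemble,
#' predicts consensus free energies for the candidate compounds, calls
#' binders at `config$delta_g_max` and applies the CNS ADMET screen.
#' Writes `predictions.csv`, `binders.csv`, `screened.csv` and
#' `repurposing_manifest.json` into `config$out_dir`.
#'
#' @param config a [run_config()] with `activity_path`, `candidate_path`
#'   and `admet_path` set.
#' @return list with `model`, `predictions`, `binders`, `screened`,
#'   invisibly.
#' @export
run_repurposing <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  activity <- stage("repurposing_ml", {
    raw <- data.table::fread(config$activity_path, data.table = FALSE,
                             colClasses = list(character = "compound_id"))
    prepare_compound_set(raw)
  })
  model <- stage("repurposing_ml",
    train_affinity_ensemble(activity, seed = config$seed,
                            grid = config$grid))
  candidates <- stage("repurposing_ml",
    data.table::fread(config$candidate_path, data.table = FALSE,
                      colClasses = list(character = "compound_id")))
  preds <- stage("repurposing_ml", predict_consensus(model, candidates))
  binders <- stage("repurposing_ml",
    call_binders(preds, config$delta_g_max))
  screened <- stage("cns_screen", {
    admet <- read_admet_table(config$admet_path)
    policy <- screen_policy(config$delta_g_max, config$bbb_min,
                            config$pgp_max)
    apply_cns_screen(binders, admet, policy)
  })
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(preds, file.path(config$out_dir, "predictions.csv"))
  data.table::fwrite(binders, file.path(config$out_dir, "binders.csv"))
  data.table::fwrite(screened, file.path(config$out_dir, "screened.csv"))
  write_manifest(
    config_manifest(config,
                    c(config$activity_path, config$candidate_path,
                      config$admet_path),
                    list(members = lapply(model$manifest$members,
                                          `[[`, "chosen"),
                         holdout_consensus_rmse =
                           model$manifest$holdout_consensus_rmse,
                         n_binders = nrow(binders),
                         n_screened = nrow(screened))),
    file.path(config$out_dir, "repurposing_manifest.json"))
  invisible(list(model = model, predictions = preds, binders = binders,
                 screened = screened))
}

#' Command-line entry point
#'
#' Subcommands: `discover-targets`, `repurpose`, `simulate`. Flags are
#' `--key value` pairs matching the [run_config()] fields (plus, for
#' `simulate`, `n_genes`, `n_modules`, `hub_per_module`, `n_compounds`,
#' `sigma`). Installed as `inst/cli/pslscreen`.
#'
#' @param args character vector (default: the command line).
#' @return exit status 0 on success, invisibly.
#' @export
pslscreen_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: pslscreen <discover-targets|repurpose|simulate> [--key value ...]")
  if (!length(args)) stop(usage, call. = FALSE)
  cmd <- args[1L]
  kv <- args[-1L]
  if (length(kv) %% 2L != 0L || !all(startsWith(kv[c(TRUE, FALSE)], "--"))) {
    stop(usage, call. = FALSE)
  }
  opts <- stats::setNames(as.list(kv[c(FALSE, TRUE)]),
                          sub("^--", "", kv[c(TRUE, FALSE)]))
  num <- suppressWarnings(lapply(opts, function(v) {
    x <- as.numeric(v); if (is.na(x)) v else x
  }))
  if (cmd == "discover-targets") {
    cfg <- do.call(run_config, num[names(num) %in% names(formals(run_config))])
    res <- run_target_discovery(cfg)
    message("final gene set: ", paste(res$intersected, collapse = ", "))
  } else if (cmd == "repurpose") {
    cfg <- do.call(run_config, num[names(num) %in% names(formals(run_config))])
    res <- run_repurposing(cfg)
    message(nrow(res$screened), " compound(s) pass the CNS screen")
  } else if (cmd == "simulate") {
    seed <- as.integer(num$seed %||% 1L)
    dir <- as.character(opts$out_dir %||% tempdir())
    net <- generate_planted_network(as.integer(num$n_genes %||% 30L),
                                    as.integer(num$n_modules %||% 2L),
                                    as.integer(num$hub_per_module %||% 1L),
                                    seed = seed, dir = dir)
    aff <- generate_affinity_dataset(as.integer(num$n_compounds %||% 500L),
                                     sigma = as.numeric(num$sigma %||% 0),
                                     seed = seed, dir = dir)
    adm <- generate_admet_table(aff$records$compound_id,
                                pass_fraction =
                                  as.numeric(num$pass_fraction %||% 0.5),
                                seed = seed, dir = dir)
    message("wrote: ", paste(c(net$deg_path, net$edge_path, aff$path,
                               adm$path), collapse = ", "))
  } else {
    stop(usage, call. = FALSE)
  }
  invisible(0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
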