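# Seeded synthetic inputs with recorded ground truth: a planted-hub gene
# network emulating a STRING-scored DEG module structure, an additive
# structure-activity dataset, and ADMET tables with a controlled pass
# rate. All generators are pure functions of (parameters, seed).

#' Generate a planted-hub labeled network
#'
#' Genes are split into modules rendered as dense near-cliques with high
#' STRING-like scores (700-990) against a sparse low-score background
#' (150-450). Each module carries `hub_per_module` hubs that are both
#' strongly dysregulated (log2FC ~ U(1.5, 3) versus U(0.1, 0.8) for the
#' rest) and highly connected: a hub touches every member of its module
#' and, with probability 1/2, each outside gene. Non-hub module pairs are
#' joined with probability 0.85, background pairs with probability 0.05.
#' All genes are up-regulated with p-values below 0.01 so the default DEG
#' selection keeps them.
#'
#' @param n_genes total genes (>= 10).
#' @param n_modules number of planted modules.
#' @param hub_per_module hubs per module.
#' @param seed integer seed.
#' @param dir output directory for the DEG CSV and edge TSV
#'   (default `tempdir()`).
#' @return a list with `deg_path`, `edge_path`, `hubs`, `modules` (named
#'   membership vector), `n_edges`, and `seed`.
#' @export
generate_planted_network <- function(n_genes, n_modules = 2L,
                                     hub_per_module = 1L, seed = 1L,
                                     dir = tempdir()) {
  if (n_genes < 10L) stop("need at least 10 genes")
  if (n_modules * (hub_per_module + 2L) > n_genes) {
    stop("infeasible: too many modules/hubs for ", n_genes, " genes")
  }
  set.seed(seed)
  genes <- sprintf("G%03d", seq_len(n_genes))
  modules <- rep(seq_len(n_modules), length.out = n_genes)
  modules <- sort(modules)
  names(modules) <- genes
  hubs <- unlist(lapply(seq_len(n_modules), function(m) {
    genes[modules == m][seq_len(hub_per_module)]
  }))
  is_hub <- genes %in% hubs

  log2fc <- ifelse(is_hub, stats::runif(n_genes, 1.5, 3),
                   stats::runif(n_genes, 0.1, 0.8))
  pvalue <- stats::runif(n_genes, 1e-6, 0.01)
  degs <- data.frame(gene = genes, log2fc = round(log2fc, 4),
                     pvalue = signif(pvalue, 4))

  a <- character(); b <- character(); s <- integer()
  add_edge <- function(x, y, lo, hi) {
    a <<- c(a, min(x, y)); b <<- c(b, max(x, y))
    s <<- c(s, sample(lo:hi, 1L))
  }
  for (i in seq_len(n_genes - 1L)) {
    for (j in (i + 1L):n_genes) {
      gi <- genes[i]; gj <- genes[j]
      same <- modules[i] == modules[j]
      any_hub <- is_hub[i] || is_hub[j]
      if (same && any_hub) {
        add_edge(gi, gj, 700L, 990L)
      } else if (same) {
        if (stats::runif(1) < 0.85) add_edge(gi, gj, 700L, 990L)
      } else if (any_hub) {
        if (stats::runif(1) < 0.5) add_edge(gi, gj, 150L, 450L)
      } else {
        if (stats::runif(1) < 0.05) add_edge(gi, gj, 150L, 450L)
      }
    }
  }
  edges <- data.frame(gene_a = a, gene_b = b, combined_score = s)
  deg_path <- file.path(dir, sprintf("planted_degs_seed%d.csv", seed))
  edge_path <- file.path(dir, sprintf("planted_edges_seed%d.tsv", seed))
  data.table::fwrite(degs, deg_path)
  data.table::fwrite(edges, edge_path, sep = "\t")
  list(deg_path = deg_path, edge_path = edge_path, hubs = hubs,
       modules = modules, n_genes = n_genes, n_edges = nrow(edges),
       seed = seed)
}

# Building blocks for synthetic molecules: drug-like cores that can accept
# a substituent at their last atom, simple carbon linkers, and capping
# tails. Concatenation core + linker + tail is a valid SMILES for every
# combination (validity is exercised by the round-trip tests).
.synth_cores <- c(
  "CC(=O)Oc1ccccc1C(=O)O",      # aspirin scaffold
  "Cn1cnc2c1c(=O)n(C)c(=O)n2C", # caffeine
  "CC(=O)Nc1ccc(O)cc1",         # paracetamol
  "CC(C)Cc1ccc(cc1)C(C)C(=O)O", # ibuprofen
  "c1ccc2ccccc2c1",             # naphthalene
  "c1ccncc1",                   # pyridine
  "C1CCNCC1",                   # piperidine
  "c1ccsc1",                    # thiophene
  "c1ccoc1",                    # furan
  "C1CCCCC1")                   # cyclohexane
.synth_tails <- c("", "O", "N", "F", "Cl", "Br", "C(=O)O", "C(=O)N",
                  "OC", "N(C)C")

#' Generate an additive structure-activity dataset
#'
#' Compounds are drawn (seeded, without replacement) from a combinatorial
#' library: core x carbon linker (0-7 atoms) x capping tail, all valid
#' drug-like SMILES. The true free energy is additive over ECFP bits:
#' a base of -9 kcal/mol plus seeded weights on up to 40 informative bits
#' (those present in 5-95% of the library), plus Gaussian noise of sd
#' `sigma`. Activities are the exact inverse free-energy conversion, so
#' the labels round-trip through [delta_g_from_activity()].
#'
#' @param n_compounds number of compounds (>= 50).
#' @param sigma sd of the free-energy noise in kcal/mol (0 = noiseless).
#' @param seed integer seed.
#' @param dir output directory for the activity CSV.
#' @param radius,n_bits ECFP parameters for the ground-truth bits.
#' @return list with `records` (the activity table), `dg_true`, the
#'   weighted `bits` and `weights`, `path` of the CSV, and `seed`.
#' @export
generate_affinity_dataset <- function(n_compounds = 500L, sigma = 0,
                                      seed = 1L, dir = tempdir(),
                                      radius = 2L, n_bits = 2048L) {
  if (n_compounds < 50L) stop("need at least 50 compounds")
  combos <- expand.grid(core = .synth_cores,
                        linker = strrep("C", 0:7),
                        tail = .synth_tails,
                        stringsAsFactors = FALSE)
  smiles_all <- paste0(combos$core, combos$linker, combos$tail)
  if (n_compounds > length(smiles_all)) {
    stop("library holds only ", length(smiles_all), " compounds")
  }
  set.seed(seed)
  smiles <- smiles_all[sort(sample.int(length(smiles_all), n_compounds))]
  X <- ecfp_matrix(smiles, radius = radius, n_bits = n_bits)
  freq <- colMeans(X)
  informative <- which(freq >= 0.05 & freq <= 0.95)
  bits <- sort(sample(informative, min(40L, length(informative))))
  weights <- stats::rnorm(length(bits), 0, 0.6)
  dg_true <- -9 + as.vector(X[, bits, drop = FALSE] %*% weights) +
    stats::rnorm(n_compounds, 0, sigma)
  records <- data.frame(
    compound_id = sprintf("CPD%04d", seq_len(n_compounds)),
    smiles = smiles,
    activity_nM = activity_from_delta_g(dg_true),
    activity_type = "IC50",
    stringsAsFactors = FALSE)
  path <- file.path(dir, sprintf("synthetic_activity_seed%d.csv", seed))
  data.table::fwrite(records, path)
  list(records = records, dg_true = dg_true, bits = bits,
       weights = weights, path = path, seed = seed)
}

#' Generate an ADMET table with a controlled pass rate
#'
#' Exactly `round(pass_fraction * n)` compounds receive probabilities
#' satisfying the default CNS policy (BBB > 0.70, both P-gp < 0.50); the
#' rest violate at least one rule, the violated rule chosen at random.
#'
#' @param compound_ids character vector of ids.
#' @param pass_fraction fraction in \[0,1\] that must pass.
#' @param seed integer seed.
#' @param dir output directory for the CSV.
#' @return list with `table`, `path`, `passing` (the ids built to pass)
#'   and `seed`.
#' @export
generate_admet_table <- function(compound_ids, pass_fraction, seed = 1L,
                                 dir = tempdir()) {
  stopifnot(pass_fraction >= 0, pass_fraction <= 1)
  set.seed(seed)
  n <- length(compound_ids)
  n_pass <- round(pass_fraction * n)
  pass <- rep(FALSE, n)
  pass[sample.int(n, n_pass)] <- TRUE
  bbb <- ifelse(pass, stats::runif(n, 0.75, 1), stats::runif(n, 0.75, 1))
  pgp_sub <- ifelse(pass, stats::runif(n, 0, 0.45), stats::runif(n, 0, 0.45))
  pgp_inh <- ifelse(pass, stats::runif(n, 0, 0.45), stats::runif(n, 0, 0.45))
  viol <- sample(1:3, n, replace = TRUE)
  bbb[!pass & viol == 1] <- stats::runif(sum(!pass & viol == 1), 0, 0.65)
  pgp_sub[!pass & viol == 2] <- stats::runif(sum(!pass & viol == 2), 0.55, 1)
  pgp_inh[!pass & viol == 3] <- stats::runif(sum(!pass & viol == 3), 0.55, 1)
  tab <- data.frame(compound_id = compound_ids,
                    bbb = round(bbb, 3), pgp_sub = round(pgp_sub, 3),
                    pgp_inh = round(pgp_inh, 3))
  path <- file.path(dir, sprintf("synthetic_admet_seed%d.csv", seed))
  data.table::fwrite(tab, path)
  list(table = tab, path = path, passing = compound_ids[pass], seed = seed)
}
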