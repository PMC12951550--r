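#' Read a differential-expression table
#'
#' Reads a CSV/TSV of differentially expressed genes (DEGs) with one row per
#' gene symbol, a log2 fold-change and a p-value. Column names are
#' configurable through `dialect`; the separator is sniffed by
#' [data.table::fread()] and gzipped files are accepted.
#'
#' Rows with an empty gene symbol or a non-numeric log2 fold-change are
#' dropped with a message stating how many were rejected. A duplicated gene
#' symbol is an error (the table must be one row per gene).
#'
#' @param path path to the table (CSV/TSV, optionally gzipped).
#' @param dialect named list mapping the roles `gene`, `log2fc`, `pvalue` to
#'   the column names used in the file.
#' @return a `data.frame` with columns `gene` (character), `log2fc`
#'   (numeric) and `pvalue` (numeric in \[0,1\]).
#' @export
read_deg_table <- function(path,
                           dialect = list(gene = "gene", log2fc = "log2fc",
                                          pvalue = "pvalue")) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("DEG table not found: ", path)
  header <- names(data.table::fread(path, header = TRUE, nrows = 0L))
  for (role in c("gene", "log2fc", "pvalue")) {
    if (!dialect[[role]] %in% header) {
      stop("DEG table is missing required column '", dialect[[role]],
           "' (role: ", role, ")")
    }
  }
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          colClasses = list(character = dialect$gene))
  gene <- trimws(as.character(dt[[dialect$gene]]))
  log2fc <- suppressWarnings(as.numeric(dt[[dialect$log2fc]]))
  pvalue <- suppressWarnings(as.numeric(dt[[dialect$pvalue]]))
  bad <- is.na(gene) | gene == "" | is.na(log2fc)
  if (any(bad)) {
    message("read_deg_table: rejected ", sum(bad),
            " row(s) with missing gene or non-numeric log2fc")
    gene <- gene[!bad]; log2fc <- log2fc[!bad]; pvalue <- pvalue[!bad]
  }
  dup <- unique(gene[duplicated(gene)])
  if (length(dup)) {
    stop("duplicate gene symbol(s) in DEG table: ",
         paste(utils::head(dup, 5L), collapse = ", "))
  }
  if (length(pvalue) && any(is.na(pvalue) | pvalue < 0 | pvalue > 1)) {
    stop("p-values must be numeric and in [0,1]")
  }
  data.frame(gene = gene, log2fc = log2fc, pvalue = pvalue,
             stringsAsFactors = FALSE)
}

#' Select the top up-regulated genes
#'
#' Keeps genes with positive log2 fold-change and p-value at most `p_max`,
#' orders them by decreasing log2 fold-change (ties: smaller p-value, then
#' gene symbol) and truncates to the `n` strongest. The defaults mirror the
#' analyzed gene set: the 200 most up-regulated genes of a cell group.
#'
#' @param records DEG `data.frame` as returned by [read_deg_table()].
#' @param n maximum number of genes to keep (default 200).
#' @param p_max p-value gate applied before the top-n cut (default 0.05).
#' @param direction `"up"` keeps log2fc > 0 (default); `"down"` keeps
#'   log2fc < 0 and ranks by |log2fc|.
#' @return the selected rows, sorted as described.
#' @export
select_top_upregulated <- function(records, n = 200L, p_max = 0.05,
                                   direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(n >= 1L)
  keep <- if (direction == "up") records$log2fc > 0 else records$log2fc < 0
  keep <- keep & records$pvalue <= p_max
  sel <- records[keep, , drop = FALSE]
  if (nrow(sel) < 2L) {
    stop("fewer than 2 genes qualify (direction=", direction,
         ", p_max=", p_max, "); the network would be degenerate")
  }
  ord <- order(-abs(sel$log2fc), sel$pvalue, sel$gene)
  sel <- sel[ord, , drop = FALSE]
  sel <- utils::head(sel, n)
  rownames(sel) <- NULL
  sel
}

#' Read a STRING-dialect interaction edge list
#'
#' Reads a TSV with two gene-identifier columns and a combined confidence
#' score in (0, 1000]. Edges are undirected: each pair is stored with the
#' lexicographically smaller symbol first and duplicates are collapsed
#' (keeping the maximum score if duplicates disagree). Self-loops are
#' dropped with a message. An optional two-column alias file maps protein
#' identifiers to gene symbols before any other processing.
#'
#' @param path path to the edge TSV (optionally gzipped).
#' @param columns named list with entries `gene_a`, `gene_b`, `score`
#'   giving the column names.
#' @param alias_path optional two-column TSV (from, to) applied to both
#'   endpoint columns.
#' @return a `data.frame` with columns `gene_a`, `gene_b` (character,
#'   `gene_a < gene_b`) and `score` (integer in (0,1000\]).
#' @export
read_interaction_edges <- function(path,
                                   columns = list(gene_a = "gene_a",
                                                  gene_b = "gene_b",
                                                  score = "combined_score"),
                                   alias_path = NULL) {
  if (!file.exists(path)) stop("edge table not found: ", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  for (role in c("gene_a", "gene_b", "score")) {
    if (!columns[[role]] %in% names(dt)) {
      stop("edge table is missing required column '", columns[[role]], "'")
    }
  }
  a <- trimws(as.character(dt[[columns$gene_a]]))
  b <- trimws(as.character(dt[[columns$gene_b]]))
  score <- suppressWarnings(as.numeric(dt[[columns$score]]))
  if (any(is.na(score) | score <= 0 | score > 1000)) {
    bad <- which(is.na(score) | score <= 0 | score > 1000)[1L]
    stop("combined score out of (0,1000] at data row ", bad,
         " (value: ", dt[[columns$score]][bad], ")")
  }
  score <- as.integer(round(score))
  if (!is.null(alias_path)) {
    al <- data.table::fread(alias_path, header = FALSE, data.table = FALSE)
    map <- stats::setNames(as.character(al[[2L]]), as.character(al[[1L]]))
    a <- ifelse(a %in% names(map), unname(map[a]), a)
    b <- ifelse(b %in% names(map), unname(map[b]), b)
  }
  loops <- a == b
  if (any(loops)) {
    message("read_interaction_edges: dropped ", sum(loops), " self-loop(s)")
    a <- a[!loops]; b <- b[!loops]; score <- score[!loops]
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  ed <- data.frame(gene_a = lo, gene_b = hi, score = score,
                   stringsAsFactors = FALSE)
  if (nrow(ed)) {
    ed <- ed[order(ed$gene_a, ed$gene_b, -ed$score), , drop = FALSE]
    ed <- ed[!duplicated(ed[c("gene_a", "gene_b")]), , drop = FALSE]
    rownames(ed) <- NULL
  }
  ed
}

#' Assemble a labeled gene network
#'
#' Combines a DEG table with interaction edges into the object the
#' topological analysis runs on: an ordered gene list, a dysregulation
#' label q(gene) = max(|log2fc|, q_floor) per gene, and the confidence
#' edges restricted to those genes. The floor keeps every label strictly
#' positive, which the sheaf construction requires (its simplex weights
#' must be nowhere zero). Genes without any edge are retained: vertices
#' never die in the confidence filtration.
#'
#' @param degs DEG `data.frame` (typically from [select_top_upregulated()]).
#' @param edges edge `data.frame` from [read_interaction_edges()].
#' @param q_floor minimum dysregulation label (default 1e-6).
#' @return an object of class `labeled_network` with elements `genes`
#'   (lexicographically sorted character vector), `q` (named numeric) and
#'   `edges` (data frame restricted to `genes`).
#' @export
build_labeled_network <- function(degs, edges, q_floor = 1e-6) {
  if (!nrow(degs)) stop("no DEGs supplied")
  stopifnot(q_floor > 0)
  genes <- sort(unique(degs$gene))
  q <- pmax(abs(degs$log2fc), q_floor)
  names(q) <- degs$gene
  q <- q[genes]
  keep <- edges$gene_a %in% genes & edges$gene_b %in% genes
  ed <- edges[keep, , drop = FALSE]
  ed <- ed[order(ed$gene_a, ed$gene_b), , drop = FALSE]
  rownames(ed) <- NULL
  structure(list(genes = genes, q = q, edges = ed),
            class = "labeled_network")
}

#' @export
print.labeled_network <- function(x, ...) {
  cat("<labeled_network> ", length(x$genes), " genes, ", nrow(x$edges),
      " edges; q in [", format(min(x$q), digits = 3), ", ",
      format(max(x$q), digits = 3), "]\n", sep = "")
  invisible(x)
}

#' Write / re-read a labeled network
#'
#' The documented on-disk dialect is a pair of TSVs: `<stem>_nodes.tsv`
#' with columns `gene`, `q` and `<stem>_edges.tsv` with columns `gene_a`,
#' `gene_b`, `score`. Writing then reading yields an identical network.
#'
#' @param network a `labeled_network`.
#' @param stem output path stem.
#' @return `write_labeled_network` returns the two paths invisibly;
#'   `read_labeled_network` returns a `labeled_network`.
#' @export
write_labeled_network <- function(network, stem) {
  nodes <- data.frame(gene = network$genes, q = unname(network$q))
  paths <- c(nodes = paste0(stem, "_nodes.tsv"),
             edges = paste0(stem, "_edges.tsv"))
  data.table::fwrite(nodes, paths[["nodes"]], sep = "\t")
  data.table::fwrite(network$edges, paths[["edges"]], sep = "\t")
  invisible(paths)
}

#' @rdname write_labeled_network
#' @export
read_labeled_network <- function(stem) {
  nodes <- data.table::fread(paste0(stem, "_nodes.tsv"), data.table = FALSE,
                             colClasses = list(character = "gene"))
  edges <- data.table::fread(paste0(stem, "_edges.tsv"), data.table = FALSE)
  if (!nrow(edges)) {
    edges <- data.frame(gene_a = character(), gene_b = character(),
                        score = integer())
  }
  edges$gene_a <- as.character(edges$gene_a)
  edges$gene_b <- as.character(edges$gene_b)
  edges$score <- as.integer(edges$score)
  q <- stats::setNames(nodes$q, nodes$gene)
  structure(list(genes = nodes$gene, q = q, edges = edges),
            class = "labeled_network")
}
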