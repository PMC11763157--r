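normalize_gene_ids <- function(x) toupper(trimws(x))

#' Intersect a transcriptome gene universe with a disease reference gene list
#'
#' Gene identifiers are matched exactly after uppercasing and whitespace
#' stripping; no alias or ortholog mapping is attempted. The result is the
#' deduplicated intersection in sorted order. An empty intersection is a
#' warning, not an error.
#'
#' @param transcriptome_genes character vector of gene ids measured in the
#'   transcriptome.
#' @param reference character vector of disease reference gene ids.
#' @return sorted character vector of shared gene ids.
#' @export
intersect_universe <- function(transcriptome_genes, reference) {
  if (length(transcriptome_genes) == 0 || length(reference) == 0)
    stop("both gene lists must be non-empty")
  shared <- sort(intersect(unique(normalize_gene_ids(transcriptome_genes)),
                           unique(normalize_gene_ids(reference))))
  if (length(shared) == 0)
    warning("no genes shared between transcriptome and reference list")
  shared
}

#' Build a disease network from a gene set and a PPI edge table
#'
#' Keeps PPI edges whose two endpoints both lie in `gene_set` and whose
#' confidence is at least `min_confidence`, then drops genes left without
#' any qualifying edge. Dropping isolated genes means the node count of the
#' network is typically smaller than the gene set that seeded it. The
#' default threshold 0.4 follows the common "medium confidence" convention
#' for interaction databases.
#'
#' @param gene_set character vector of gene ids (e.g. from
#'   [intersect_universe()]).
#' @param edges data.frame with columns `gene_a`, `gene_b`, `confidence`
#'   (confidence in [0, 1]).
#' @param min_confidence minimum edge confidence kept (in [0, 1]).
#' @return object of class `disease_network`: list with `graph` (igraph),
#'   `nodes` (data.frame: `gene`, `degree`) and `min_confidence`.
#' @export
build_network <- function(gene_set, edges, min_confidence = 0.4) {
  if (min_confidence < 0 || min_confidence > 1)
    stop("min_confidence must lie in [0, 1]")
  stopifnot(all(c("gene_a", "gene_b", "confidence") %in% names(edges)))
  gene_set <- unique(normalize_gene_ids(gene_set))
  ea <- normalize_gene_ids(edges$gene_a)
  eb <- normalize_gene_ids(edges$gene_b)
  keep <- ea %in% gene_set & eb %in% gene_set &
    edges$confidence >= min_confidence & ea != eb
  ea <- ea[keep]; eb <- eb[keep]; conf <- edges$confidence[keep]
  # collapse duplicate unordered pairs, keeping the maximum confidence
  key <- ifelse(ea < eb, paste(ea, eb, sep = "\r"), paste(eb, ea, sep = "\r"))
  if (anyDuplicated(key)) {
    ord <- order(key, -conf)
    first <- !duplicated(key[ord])
    ea <- ea[ord][first]; eb <- eb[ord][first]; conf <- conf[ord][first]
  }
  if (length(ea) == 0)
    stop("no edges survive filtering; min_confidence = ", min_confidence,
         " may be too high or the gene set too small")
  g <- igraph::graph_from_data_frame(
    data.frame(from = ea, to = eb, confidence = conf,
               stringsAsFactors = FALSE),
    directed = FALSE
  )
  deg <- igraph::degree(g)
  nodes <- data.frame(gene = igraph::V(g)$name, degree = as.integer(deg),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$gene), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(graph = g, nodes = nodes, min_confidence = min_confidence),
            class = "disease_network")
}

#' @export
print.disease_network <- function(x, ...) {
  cat(sprintf("Disease network: %d nodes, %d edges (confidence >= %g)\n",
              nrow(x$nodes), igraph::ecount(x$graph), x$min_confidence))
  if (!is.null(x$nodes$ntra_rank))
    cat("  NTRA ranking attached (rank 1 = most salient node)\n")
  invisible(x)
}

#' Rank network nodes by combined topology and transcriptome salience
#'
#' A network-topology and transcriptomics-based ranking: each node's score is
#' the sum of two z-scores computed over the network's nodes, one for the
#' magnitude of its disease log2 fold change and one for log(degree + 1).
#' Rank 1 is the highest score; ties are broken lexicographically by gene id.
#' This additive z-score heuristic is a declared stand-in for published NTRA
#' rankings, whose exact formula is not reproduced here.
#'
#' @param network `disease_network` from [build_network()].
#' @param disease_log2fc named numeric vector of disease log2 fold changes
#'   (sham-vs-model contrast), covering every network node.
#' @return the network with `disease_log2fc`, `ntra_score` and `ntra_rank`
#'   columns added to `$nodes` (ntra_rank is a permutation of 1..n_nodes).
#' @export
ntra_rank <- function(network, disease_log2fc) {
  stopifnot(inherits(network, "disease_network"))
  names(disease_log2fc) <- normalize_gene_ids(names(disease_log2fc))
  nodes <- network$nodes
  lfc <- disease_log2fc[nodes$gene]
  if (anyNA(lfc))
    stop("disease_log2fc missing for node(s): ",
         paste(utils::head(nodes$gene[is.na(lfc)], 5), collapse = ", "))
  zsafe <- function(v, what) {
    s <- stats::sd(v)
    if (is.na(s) || s == 0) {
      warning("zero variance in ", what, "; its z-score component set to 0")
      return(rep(0, length(v)))
    }
    (v - mean(v)) / s
  }
  score <- zsafe(abs(lfc), "|disease log2FC|") +
    zsafe(log(nodes$degree + 1), "log(degree + 1)")
  ord <- order(-score, nodes$gene)
  rank <- integer(length(score))
  rank[ord] <- seq_along(ord)
  nodes$disease_log2fc <- as.numeric(lfc)
  nodes$ntra_score <- score
  nodes$ntra_rank <- rank
  network$nodes <- nodes
  network
}

#' Read a gene list from a text file (one id per line)
#'
#' @param path file path; blank lines are skipped.
#' @return character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' Read a PPI edge table from TSV or SIF
#'
#' TSV files must carry a header with columns `gene_a`, `gene_b`,
#' `confidence`. SIF files (`a relation b` whitespace-separated) get
#' confidence 1 for every edge.
#'
#' @param path file path.
#' @param format `"tsv"` (default) or `"sif"`.
#' @return data.frame with `gene_a`, `gene_b`, `confidence`.
#' @export
read_edge_table <- function(path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("gene_a", "gene_b", "confidence") %in% names(df)))
    df[, c("gene_a", "gene_b", "confidence")]
  } else {
    lines <- readLines(path)
    parts <- strsplit(trimws(lines[nzchar(trimws(lines))]), "[ \t]+")
    bad <- vapply(parts, length, 1L) < 3
    if (any(bad)) stop("malformed SIF line(s)")
    data.frame(gene_a = vapply(parts, `[`, "", 1),
               gene_b = vapply(parts, `[`, "", 3),
               confidence = 1, stringsAsFactors = FALSE)
  }
}

#' Write a disease network to GraphML, edge-list TSV, and node-attribute TSV
#'
#' @param network `disease_network` object.
#' @param prefix output path prefix; writes `<prefix>.graphml`,
#'   `<prefix>_edges.tsv` and `<prefix>_nodes.tsv`.
#' @return invisibly, the paths written.
#' @export
write_network <- function(network, prefix) {
  stopifnot(inherits(network, "disease_network"))
  paths <- c(graphml = paste0(prefix, ".graphml"),
             edges = paste0(prefix, "_edges.tsv"),
             nodes = paste0(prefix, "_nodes.tsv"))
  igraph::write_graph(network$graph, paths["graphml"], format = "graphml")
  ed <- igraph::as_data_frame(network$graph, what = "edges")
  names(ed) <- c("gene_a", "gene_b", "confidence")
  utils::write.table(ed, paths["edges"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(network$nodes, paths["nodes"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
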