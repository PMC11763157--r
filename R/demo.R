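# Bundled synthetic demo study. All inputs are generated in code with planted
# ground truth emulating a rodent myocardial-infarction combination-therapy
# study at full scale: a 32,545-gene transcriptome universe, a
# 1641-gene disease reference list sharing 1539 genes with it, a 1447-node
# disease network after isolated genes are dropped, per-arm recovery counts
# of 902 / 804 / 437, combination-specific / differential / union gene sets
# of 250 / 492 / 537, and 70 restored metabolites. The gene identities and
# network wiring are synthetic; only the planted counts are meaningful.

#' Planted EoR matrix of the bundled demo study
#'
#' A 1447 x 3 matrix of planted EoR values (percent) for arms
#' `combination`, `cf`, `bbp`, built from seven constant blocks so that the
#' recovery accounting is exact by construction:
#' 902/804/437 genes recovered per arm, 250 combination-specific genes,
#' 492 differential genes at a 20-point margin, overlapping in 205 genes for
#' a union of 537.
#'
#' @param genes optional character vector of 1447 gene ids for the rownames.
#' @return numeric matrix with columns `combination`, `cf`, `bbp`.
#' @export
demo_recovery_matrix <- function(genes = NULL) {
  blocks <- rbind(
    # n, combination, cf, bbp
    c(205, 50, -10, -10),  # specific AND differential
    c(45, 10, -5, -50),    # specific only (cf margin 15 <= 20)
    c(287, 80, 30, 30),    # differential only (monotherapies recovered)
    c(150, 60, 55, 50),    # recovered everywhere, margins too small
    c(215, 60, 55, -5),    # combination + cf recovered, margins too small
    c(152, -10, 40, -10),  # cf-only recovery
    c(393, -20, -10, -10)  # no recovery anywhere
  )
  m <- blocks[rep(seq_len(nrow(blocks)), blocks[, 1]), 2:4, drop = FALSE]
  colnames(m) <- c("combination", "cf", "bbp")
  if (!is.null(genes)) {
    stopifnot(length(genes) == nrow(m))
    rownames(m) <- genes
  }
  m
}

#' Synthetic network inputs of the bundled demo study
#'
#' Generates a transcriptome universe of 32,545 gene ids, a disease reference
#' list of 1641 ids of which 1539 are shared with the universe, and a PPI
#' edge table over the shared genes in which exactly 92 genes receive only
#' sub-threshold edges (confidence < 0.4) while the remaining 1447 are
#' guaranteed at least one qualifying edge — so [build_network()] at the
#' default confidence 0.4 yields a 1447-node network.
#'
#' @param seed integer seed.
#' @param mean_degree target mean degree of the generated edge table
#'   (default 103; confidences are uniform on [0, 1], so the
#'   medium-confidence subnetwork retains about 60% of the edges, an edge
#'   count of the order of 4.5e4).
#' @return list with `universe`, `reference`, `edges`, `network_genes`
#'   (the 1447 connectable ids), `isolated_genes` (the 92 sub-threshold ids).
#' @export
demo_network_inputs <- function(seed = 1, mean_degree = 103) {
  universe <- sprintf("G%05d", seq_len(32545))
  set.seed(split_seed(seed, "demo_network"))
  shared <- sort(sample(universe, 1539))
  reference <- sort(c(shared, sprintf("REFONLY%04d", seq_len(102))))
  connected <- sort(sample(shared, 1447))
  isolated <- setdiff(shared, connected)

  edges <- gen_ppi(connected, mean_degree, seed = split_seed(seed, "demo_ppi"))
  # guarantee every connected gene at least one edge at confidence >= 0.4
  set.seed(split_seed(seed, "demo_patch"))
  deg_ok <- unique(c(edges$gene_a[edges$confidence >= 0.4],
                     edges$gene_b[edges$confidence >= 0.4]))
  missing <- setdiff(connected, deg_ok)
  if (length(missing)) {
    partner <- sample(setdiff(connected, missing),
                      length(missing), replace = TRUE)
    edges <- rbind(edges, data.frame(
      gene_a = missing, gene_b = partner,
      confidence = stats::runif(length(missing), 0.4, 1),
      stringsAsFactors = FALSE))
  }
  # the 92 isolated genes only get sub-threshold edges
  lowconf <- data.frame(
    gene_a = isolated,
    gene_b = sample(connected, length(isolated), replace = TRUE),
    confidence = stats::runif(length(isolated), 0, 0.39),
    stringsAsFactors = FALSE
  )
  edges <- rbind(edges, lowconf)
  list(universe = universe, reference = reference, edges = edges,
       network_genes = connected, isolated_genes = isolated)
}

#' Full input bundle of the demo study
#'
#' Assembles every input the pipeline consumes: the network inputs, a
#' zero-expression-noise study whose planted EoR matrix covers the 1447
#' network genes (so the recovery accounting is exact), plate-assay readouts
#' with planted effects (0.3, 0.4, 0.8) giving a planted Bliss combination
#' index of 0.725, a metabolite study with 70 planted restored features, and
#' paired taxon/metabolite tables with a planted 4 x 4 Spearman block.
#'
#' @param seed integer seed.
#' @return list with `network`, `study`, `readouts`, `metabolites`, `paired`,
#'   and `planted` (the headline planted quantities).
#' @export
demo_inputs <- function(seed = 1) {
  net <- demo_network_inputs(seed)
  planted_eor <- demo_recovery_matrix(net$network_genes)
  design <- study_design(
    arms = c("cf", "bbp", "combination"),
    replicates = 6,
    n_genes = length(net$universe),
    n_disease_genes = 1539,
    planted_eor = planted_eor,
    noise_cv = 0,
    seed = split_seed(seed, "demo_expression"),
    genes = net$universe
  )
  study <- gen_expression_study(design)
  effects <- c(cf = 0.3, bbp = 0.4, combination = 0.8)
  readouts <- gen_assay(effects, n_replicates = 6, noise_sd = 0.02,
                        seed = split_seed(seed, "demo_assay"))
  mets <- gen_metabolite_study(n_restored = 70, n_disease_only = 40,
                               n_same_sign = 20, n_null = 200,
                               replicates = 6, lfc = 2, noise_cv = 0.1,
                               seed = split_seed(seed, "demo_metabolites"))
  # planted taxon-metabolite Spearman block: one beneficial genus positively
  # associated with the restored peptide-like metabolites, three harmful
  # genera negatively associated. Magnitudes are capped so the joint copula
  # correlation (zero within-block) stays positive semi-definite: each
  # feature's latent cross-correlation vector must have norm <= 1.
  rho <- matrix(c(
    #   hemorphin  glutamylalanine  oleoylcholine  isokobusone
    0.40, 0.35, 0.15, 0.10,     # lactobacillus-like
    -0.30, -0.10, -0.30, -0.05, # helicobacter-like
    -0.25, -0.25, -0.25, -0.10, # bilophila-like
    -0.30, -0.30, -0.10, -0.05  # butyricimonas-like
  ), nrow = 4, byrow = TRUE)
  paired <- gen_paired_omics(4, 4, n_samples = 30, rho = rho,
                             seed = split_seed(seed, "demo_paired"))
  list(
    network = net, study = study, readouts = readouts, metabolites = mets,
    paired = paired,
    planted = list(
      shared_genes = 1539, network_nodes = 1447,
      recovered = c(combination = 902, cf = 804, bbp = 437),
      specific = 250, differential = 492, union = 537,
      effects = effects,
      ci = unname((0.3 + 0.4 - 0.3 * 0.4) / 0.8),
      restored = 70, rho = rho
    )
  )
}
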