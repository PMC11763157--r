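#' Build a pipeline run configuration
#'
#' Collects every threshold and mode switch of the pipeline in one validated
#' object. `inputs` may be `NULL` (the bundled synthetic demo study is
#' generated from `seed`) or a list as returned by [demo_inputs()].
#'
#' @param seed master integer seed.
#' @param out_dir optional output directory; when given, every stage persists
#'   its tables (TSV/GraphML/JSON) there.
#' @param min_confidence PPI edge confidence threshold in [0, 1].
#' @param eor_threshold recovery classification threshold (EoR percent).
#' @param delta differential-selection margin (see [select_differential()]).
#' @param delta_scale `"fraction"` or `"percent"`.
#' @param differential_mode `"all"` or `"any"`.
#' @param pseudo_count pseudo-count for expression fold changes.
#' @param p_thresh,lfc_thresh,score_thresh metabolite screening gates.
#' @param additive_tol additive band half-width for CI classification.
#' @param restored_mode `"significant"` or `"direction_only"`.
#' @param arms monotherapy arm names.
#' @param combo combination arm name.
#' @param n_boot bootstrap replicates for the synergy CI interval (0 = none).
#' @param inputs optional input bundle (see above).
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1, out_dir = NULL,
                       min_confidence = 0.4, eor_threshold = 0,
                       delta = 0.2, delta_scale = "fraction",
                       differential_mode = "all", pseudo_count = 0,
                       p_thresh = 0.05, lfc_thresh = 0.2,
                       score_thresh = 38.1, additive_tol = 0.05,
                       restored_mode = "significant",
                       arms = c("cf", "bbp"), combo = "combination",
                       n_boot = 0, inputs = NULL) {
  cfg <- list(seed = seed, out_dir = out_dir,
              min_confidence = min_confidence,
              eor_threshold = eor_threshold, delta = delta,
              delta_scale = delta_scale,
              differential_mode = differential_mode,
              pseudo_count = pseudo_count, p_thresh = p_thresh,
              lfc_thresh = lfc_thresh, score_thresh = score_thresh,
              additive_tol = additive_tol, restored_mode = restored_mode,
              arms = arms, combo = combo, n_boot = n_boot, inputs = inputs)
  class(cfg) <- "run_config"
  cfg
}

#' Validate a run configuration
#'
#' Checks every threshold range and referenced path at once and returns all
#' problems found (an empty character vector means the configuration is
#' valid). Errors are the return value, not conditions.
#'
#' @param config a [run_config()].
#' @return character vector of problems (length 0 if valid).
#' @export
validate_config <- function(config) {
  errs <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(is.numeric(config$seed) && length(config$seed) == 1,
      "seed must be a single number")
  chk(config$min_confidence >= 0 && config$min_confidence <= 1,
      "min_confidence must lie in [0, 1]")
  chk(config$delta >= 0, "delta must be non-negative")
  chk(config$delta_scale %in% c("fraction", "percent"),
      "delta_scale must be 'fraction' or 'percent'")
  chk(config$differential_mode %in% c("all", "any"),
      "differential_mode must be 'all' or 'any'")
  chk(config$pseudo_count >= 0, "pseudo_count must be non-negative")
  chk(config$p_thresh > 0 && config$p_thresh <= 1,
      "p_thresh must lie in (0, 1]")
  chk(config$additive_tol >= 0, "additive_tol must be non-negative")
  chk(config$restored_mode %in% c("significant", "direction_only"),
      "restored_mode must be 'significant' or 'direction_only'")
  chk(config$n_boot >= 0, "n_boot must be non-negative")
  chk(!(config$combo %in% config$arms),
      "combo arm must not be listed among the monotherapy arms")
  for (p in config$inputs[vapply(config$inputs, is.character, TRUE)]) {
    if (length(p) == 1 && !file.exists(p))
      errs <- c(errs, paste0("input path does not exist: ", p))
  }
  errs
}

#' Run the full analysis pipeline
#'
#' Executes, in dependency order: synthetic-data generation (or input
#' loading), gene-universe intersection, disease-network construction with
#' NTRA ranking, fold-change and EoR scoring with recovery accounting and
#' gene-set selection, Bliss synergy analysis of the plate assay, metabolite
#' screening with restored-feature identification, and taxon-metabolite
#' Spearman association. Deterministic given the seed. When
#' `config$out_dir` is set, each stage's outputs and a summary JSON are
#' persisted there.
#'
#' @param config a [run_config()]; validation problems abort the run before
#'   any computation.
#' @return object of class `run_summary` with, per stage, the counts and
#'   headline statistics, plus the stage outputs themselves in `$stages`.
#' @export
run_all <- function(config = run_config()) {
  errs <- validate_config(config)
  if (length(errs))
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "))
  inputs <- if (is.null(config$inputs)) demo_inputs(config$seed)
            else config$inputs

  # --- network stage ---------------------------------------------------
  net_in <- inputs$network
  shared <- intersect_universe(net_in$universe, net_in$reference)
  network <- build_network(shared, net_in$edges,
                           min_confidence = config$min_confidence)

  # --- EoR stage --------------------------------------------------------
  study <- inputs$study
  fc <- compute_fold_changes(study$expression, study$samples,
                             arms = c(config$arms, config$combo),
                             pseudo_count = config$pseudo_count)
  fc_net <- fc[fc$gene %in% network$nodes$gene, , drop = FALSE]
  eor_tab <- eor_table(fc_net, arms = c(config$arms, config$combo),
                       threshold = config$eor_threshold)
  rates <- lapply(c(config$arms, config$combo), function(a)
    recovery_rate(eor_tab, a, threshold = config$eor_threshold))
  names(rates) <- c(config$arms, config$combo)
  specific <- select_specific(eor_tab, config$combo, config$arms)
  differential <- select_differential(eor_tab, config$combo, config$arms,
                                      delta = config$delta,
                                      delta_scale = config$delta_scale,
                                      mode = config$differential_mode)
  union_set <- select_union(specific, differential)

  lfc_net <- stats::setNames(log2(fc_net$fc_disease), fc_net$gene)
  network <- ntra_rank(network, lfc_net)

  # --- synergy stage ----------------------------------------------------
  synergy <- synergy_analysis(inputs$readouts, config$arms, config$combo,
                              additive_tol = config$additive_tol,
                              n_boot = config$n_boot,
                              seed = split_seed(config$seed, "bootstrap"))

  # --- metabolite stage -------------------------------------------------
  mets <- inputs$metabolites
  treatment <- setdiff(unique(mets$samples$group), c("sham", "model"))[1]
  screen_disease <- differential_screen(
    mets$abundance, mets$samples, "model", "sham", scores = mets$scores,
    p_thresh = config$p_thresh, lfc_thresh = config$lfc_thresh,
    score_thresh = config$score_thresh)
  screen_treatment <- differential_screen(
    mets$abundance, mets$samples, treatment, "model", scores = mets$scores,
    p_thresh = config$p_thresh, lfc_thresh = config$lfc_thresh,
    score_thresh = config$score_thresh)
  restored <- restored_features(screen_disease, screen_treatment,
                                mode = config$restored_mode)

  # --- association stage ------------------------------------------------
  assoc <- spearman_matrix(inputs$paired$taxa, inputs$paired$metabolites)

  stages <- list(network = network, fold_changes = fc, eor = eor_tab,
                 specific = specific, differential = differential,
                 union = union_set, synergy = synergy,
                 screen_disease = screen_disease,
                 screen_treatment = screen_treatment, restored = restored,
                 association = assoc)
  summary <- structure(list(
    seed = config$seed,
    config = config[setdiff(names(config), "inputs")],
    version = as.character(utils::packageVersion("eornet")),
    shared_genes = length(shared),
    network_nodes = nrow(network$nodes),
    network_edges = igraph::ecount(network$graph),
    recovery = lapply(rates, function(r)
      list(count = r$count, total = r$total, percent = r$percent)),
    n_specific = length(specific),
    n_differential = length(differential),
    n_union = length(union_set),
    CI = synergy$CI,
    classification = synergy$classification,
    n_screened_disease = sum(screen_disease$pass),
    n_screened_treatment = sum(screen_treatment$pass),
    n_restored = length(restored),
    stages = stages
  ), class = "run_summary")

  if (!is.null(config$out_dir)) persist_run(summary, config$out_dir)
  summary
}

#' @export
print.run_summary <- function(x, ...) {
  cat("Pipeline run summary (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  Shared genes: %d; network: %d nodes, %d edges\n",
              x$shared_genes, x$network_nodes, x$network_edges))
  for (a in names(x$recovery)) {
    r <- x$recovery[[a]]
    cat(sprintf("  Recovery [%s]: %d / %d = %.2f%%\n",
                a, r$count, r$total, r$percent))
  }
  cat(sprintf("  Gene sets: %d specific, %d differential, %d union\n",
              x$n_specific, x$n_differential, x$n_union))
  cat(sprintf("  Synergy: CI = %.4f (%s)\n", x$CI, x$classification))
  cat(sprintf("  Metabolites: %d disease-differential, %d restored\n",
              x$n_screened_disease, x$n_restored))
  invisible(x)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

persist_run <- function(summary, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  st <- summary$stages
  write_network(st$network, file.path(out_dir, "network"))
  write_tsv(st$fold_changes, file.path(out_dir, "fold_changes.tsv"))
  write_tsv(st$eor, file.path(out_dir, "eor.tsv"))
  writeLines(st$specific, file.path(out_dir, "genes_specific.txt"))
  writeLines(st$differential, file.path(out_dir, "genes_differential.txt"))
  writeLines(st$union, file.path(out_dir, "genes_union.txt"))
  write_tsv(st$screen_disease, file.path(out_dir, "screen_disease.tsv"))
  write_tsv(st$screen_treatment, file.path(out_dir, "screen_treatment.tsv"))
  writeLines(st$restored, file.path(out_dir, "metabolites_restored.txt"))
  rho <- st$association$rho
  write_tsv(data.frame(taxon = rownames(rho), rho, check.names = FALSE),
            file.path(out_dir, "association_rho.tsv"))
  js <- summary[setdiff(names(summary), "stages")]
  jsonlite::write_json(js, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(out_dir)
}
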