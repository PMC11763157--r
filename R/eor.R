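#' Efficiency of recovery (EoR) for a treated gene
#'
#' Quantifies how completely a treatment restores a gene whose expression was
#' perturbed by disease modelling. Both fold changes are linear ratios taken
#' against the model group: `fc_arm` = mean(treatment)/mean(model) and
#' `fc_disease` = mean(sham)/mean(model). Their ratio is expressed on a
#' percent scale (ratio 1 = 100%), and
#'
#'   EoR = 100 - |100 - 100 * fc_arm / fc_disease|
#'
#' so EoR = 100 means the treatment fold change coincides with the sham/model
#' fold change (complete recovery), EoR in (0, 100) partial recovery, and
#' EoR <= 0 no recovery or over-correction past twice the sham level. Values
#' are not clamped below: negative EoR carries over-correction information.
#'
#' @param fc_arm positive linear fold change treatment/model (vector).
#' @param fc_disease positive linear fold change sham/model (vector, recycled).
#' @return numeric vector of EoR values in percent units, each <= 100.
#' @examples
#' eor(2, 2)      # 100: complete recovery
#' eor(1, 2)      # 50
#' eor(4, 2)      # 0: twice the sham-level shift
#' eor(6, 2)      # -100: strong over-correction
#' @export
eor <- function(fc_arm, fc_disease) {
  if (any(!is.finite(fc_arm)) || any(!is.finite(fc_disease)))
    stop("fold changes must be finite")
  if (any(fc_arm <= 0) || any(fc_disease <= 0))
    stop("fold changes must be positive linear ratios")
  100 - abs(100 - 100 * fc_arm / fc_disease)
}

#' Fold changes of group means from an expression table
#'
#' Plain ratio-of-means fold changes on the linear scale, with a pseudo-count
#' guarding against zero group means. For the disease contrast the ratio is
#' sham/model; for each treatment arm it is arm/model, matching the contrasts
#' that enter [eor()]. No shrinkage or dispersion modelling is applied; this
#' is a deliberate, documented divergence from moderated differential
#' expression estimators.
#'
#' @param expr numeric matrix, genes x samples (non-negative). Row names are
#'   gene ids, column names sample ids.
#' @param samples data.frame with columns `sample` and `group`, one row per
#'   column of `expr`.
#' @param sham,model group labels for the disease contrast.
#' @param arms character vector of treatment-arm group labels.
#' @param pseudo_count non-negative value added to every group mean
#'   (default 0.5).
#' @return data.frame with columns `gene`, `fc_disease`, and `fc_<arm>` for
#'   each arm; all ratios positive, linear scale.
#' @export
compute_fold_changes <- function(expr, samples, sham = "sham", model = "model",
                                 arms, pseudo_count = 0.5) {
  expr <- as.matrix(expr)
  if (any(expr < 0)) stop("expression values must be non-negative")
  if (is.null(rownames(expr))) stop("expression matrix needs gene row names")
  stopifnot(all(c("sample", "group") %in% names(samples)))
  samples <- samples[match(colnames(expr), samples$sample), , drop = FALSE]
  if (anyNA(samples$sample))
    stop("every expression column must appear in the sample sheet")
  groups <- c(sham, model, arms)
  for (g in groups) {
    n <- sum(samples$group == g)
    if (n == 0) stop("group not found in sample sheet: ", g)
    if (n < 2) stop("group '", g, "' has fewer than 2 samples")
  }
  gmean <- function(g) rowMeans(expr[, samples$group == g, drop = FALSE])
  m_model <- gmean(model) + pseudo_count
  out <- data.frame(
    gene = rownames(expr),
    fc_disease = (gmean(sham) + pseudo_count) / m_model,
    stringsAsFactors = FALSE
  )
  for (a in arms) out[[paste0("fc_", a)]] <- (gmean(a) + pseudo_count) / m_model
  rownames(out) <- NULL
  out
}

#' Per-gene EoR table across treatment arms
#'
#' Applies [eor()] to every gene and arm of a fold-change table and attaches
#' recovery flags (`recovered_<arm>` is `eor_<arm> > threshold`, strictly).
#'
#' @param fc fold-change table from [compute_fold_changes()] (columns `gene`,
#'   `fc_disease`, `fc_<arm>`).
#' @param arms arms to score; default all `fc_<arm>` columns present.
#' @param threshold recovery classification threshold on the EoR percent
#'   scale (default 0, strict inequality).
#' @return data.frame with `gene`, `eor_<arm>` and `recovered_<arm>` columns.
#' @export
eor_table <- function(fc, arms = NULL, threshold = 0) {
  if (is.null(arms)) {
    arms <- sub("^fc_", "", setdiff(grep("^fc_", names(fc), value = TRUE),
                                    "fc_disease"))
  }
  if (length(arms) == 0) stop("no treatment arms found")
  out <- data.frame(gene = fc$gene, stringsAsFactors = FALSE)
  for (a in arms) {
    col <- paste0("fc_", a)
    if (is.null(fc[[col]])) stop("missing fold-change column: ", col)
    e <- eor(fc[[col]], fc$fc_disease)
    out[[paste0("eor_", a)]] <- e
    out[[paste0("recovered_", a)]] <- e > threshold
  }
  out
}

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Recovery rate of a treatment arm over the disease network genes
#'
#' Counts genes whose EoR exceeds the threshold (strictly) and reports the
#' percent of the table, rounded half-up to 2 decimals (so 902 of 1447 genes
#' prints as 62.34).
#'
#' @param eor_tab table from [eor_table()].
#' @param arm arm name.
#' @param threshold EoR threshold in percent units (default 0).
#' @return list with `count`, `total`, `percent`.
#' @export
recovery_rate <- function(eor_tab, arm, threshold = 0) {
  if (nrow(eor_tab) == 0) stop("empty EoR table")
  col <- paste0("eor_", arm)
  if (is.null(eor_tab[[col]])) stop("arm not present: ", arm)
  count <- sum(eor_tab[[col]] > threshold)
  total <- nrow(eor_tab)
  list(count = count, total = total,
       percent = round_half_up(100 * count / total, 2))
}

#' Genes recovery-regulated only by the combination treatment
#'
#' Selects genes with EoR > 0 under the combination arm and EoR <= 0 under
#' every monotherapy arm: the combination-specific recovery set of a Venn
#' comparison between the combination and its component monotherapies.
#'
#' @param eor_tab table from [eor_table()].
#' @param combo_arm combination arm name.
#' @param mono_arms character vector of monotherapy arm names.
#' @return character vector of gene ids.
#' @export
select_specific <- function(eor_tab, combo_arm, mono_arms) {
  if (combo_arm %in% mono_arms)
    stop("combination arm cannot be listed among the monotherapy arms")
  e <- function(a) {
    col <- paste0("eor_", a)
    if (is.null(eor_tab[[col]])) stop("arm not present: ", a)
    eor_tab[[col]]
  }
  keep <- e(combo_arm) > 0
  for (a in mono_arms) keep <- keep & (e(a) <= 0)
  eor_tab$gene[keep]
}

#' Genes whose combination EoR exceeds every monotherapy EoR by a margin
#'
#' Selects genes where `eor(combo) - eor(mono) > delta` for every (default)
#' or any monotherapy arm. `delta` is interpreted on a fraction scale by
#' default: EoR values are percent, so `delta = 0.2` demands a margin of 20
#' percentage points (`delta_scale = "percent"` reads `delta` directly in
#' percentage points instead; the threshold's intended scale is ambiguous in
#' typical reports, so both are provided).
#'
#' @param eor_tab table from [eor_table()].
#' @param combo_arm combination arm name.
#' @param mono_arms monotherapy arm names.
#' @param delta non-negative margin (default 0.2).
#' @param delta_scale `"fraction"` (default; margin = 100 * delta percentage
#'   points) or `"percent"` (margin = delta points).
#' @param mode `"all"` (default): margin exceeded against every mono arm;
#'   `"any"`: against at least one.
#' @return character vector of gene ids.
#' @export
select_differential <- function(eor_tab, combo_arm, mono_arms, delta = 0.2,
                                delta_scale = c("fraction", "percent"),
                                mode = c("all", "any")) {
  delta_scale <- match.arg(delta_scale)
  mode <- match.arg(mode)
  if (delta < 0) stop("delta must be non-negative")
  margin <- if (delta_scale == "fraction") 100 * delta else delta
  e <- function(a) {
    col <- paste0("eor_", a)
    if (is.null(eor_tab[[col]])) stop("arm not present: ", a)
    eor_tab[[col]]
  }
  ec <- e(combo_arm)
  hits <- vapply(mono_arms, function(a) ec - e(a) > margin,
                 logical(nrow(eor_tab)))
  hits <- matrix(hits, nrow = nrow(eor_tab))
  keep <- if (mode == "all") rowSums(hits) == length(mono_arms)
          else rowSums(hits) > 0
  eor_tab$gene[keep]
}

#' Union of the combination-specific and differential gene sets
#'
#' Set union after duplicate elimination; the size obeys inclusion-exclusion
#' (|A| + |B| - |A intersect B|).
#'
#' @param specific,differential character vectors of gene ids.
#' @return sorted character vector of unique gene ids.
#' @export
select_union <- function(specific, differential) {
  sort(unique(c(specific, differential)))
}
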