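# Vectorized Welch two-sample t-test over the rows of two matrices.
# Returns two-sided p-values; rows with zero variance in both groups fall
# back to the exact-equality rule (p = 1 if the means are equal, p = 0
# flagged degenerate otherwise).
welch_rows <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  degen <- se2 == 0
  if (any(degen)) {
    warning(sum(degen), " feature(s) with zero within-group variance; ",
            "p set by exact-equality rule")
    p[degen] <- ifelse(ma[degen] == mb[degen], 1, 0)
  }
  list(p = p, mean_a = ma, mean_b = mb, degenerate = degen)
}

#' Differential feature screening with significance, fold-change and
#' annotation-score gates
#'
#' Per-feature Welch (unequal-variance) two-sample t-test between two groups,
#' combined with a log2 fold-change gate and an annotation-score gate. A
#' feature passes when all three hold: `p < p_thresh`,
#' `|log2fc| > lfc_thresh`, `score >= score_thresh`. Any gate can be
#' disabled by setting its threshold permissively (e.g. `p_thresh = 1`,
#' `lfc_thresh = 0` is *not* off — use `-Inf`; `score_thresh = -Inf`).
#' The fold change is the ratio of group means (groupA over groupB) with a
#' pseudo-count of half the smallest nonzero abundance, then log2.
#'
#' @param table numeric matrix, features x samples (non-negative).
#' @param samples data.frame with `sample`, `group`.
#' @param groupA,groupB group labels; the fold change is A over B.
#' @param scores named numeric vector of annotation scores per feature
#'   (missing features get -Inf, i.e. they fail the score gate unless it is
#'   disabled).
#' @param p_thresh significance gate (default 0.05, strict <).
#' @param lfc_thresh |log2 fold change| gate (default 0.2, strict >).
#' @param score_thresh annotation-score gate (default 38.1, >=).
#' @return data.frame with `feature`, `p`, `log2fc`, `score`, `pass`,
#'   `degenerate`.
#' @export
differential_screen <- function(table, samples, groupA, groupB,
                                scores = NULL, p_thresh = 0.05,
                                lfc_thresh = 0.2, score_thresh = 38.1) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("abundances must be non-negative")
  stopifnot(all(c("sample", "group") %in% names(samples)))
  samples <- samples[match(colnames(table), samples$sample), , drop = FALSE]
  ia <- which(samples$group == groupA)
  ib <- which(samples$group == groupB)
  if (length(ia) < 2 || length(ib) < 2)
    stop("each group needs at least 2 samples")
  wt <- welch_rows(table[, ia, drop = FALSE], table[, ib, drop = FALSE])
  nz <- table[table > 0]
  pc <- if (length(nz)) min(nz) / 2 else 0.5
  lfc <- log2((wt$mean_a + pc) / (wt$mean_b + pc))
  feat <- rownames(table)
  if (is.null(feat)) feat <- sprintf("feature_%d", seq_len(nrow(table)))
  sc <- if (is.null(scores)) rep(-Inf, nrow(table))
        else ifelse(is.na(scores[feat]), -Inf, scores[feat])
  data.frame(
    feature = feat,
    p = wt$p,
    log2fc = lfc,
    score = as.numeric(sc),
    pass = wt$p < p_thresh & abs(lfc) > lfc_thresh & sc >= score_thresh,
    degenerate = wt$degenerate,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Features restored by treatment
#'
#' A feature is restored when it passes the screen in both the disease
#' contrast (model vs sham) and the treatment contrast (treatment vs model)
#' and the two log2 fold changes have opposite signs — the treatment moves
#' the feature back toward the sham level. With
#' `mode = "direction_only"`, the treatment contrast needs only the sign
#' reversal (and a nonzero fold change), not significance.
#'
#' @param diff_disease screen results for the model-vs-sham contrast.
#' @param diff_treatment screen results for the treatment-vs-model contrast
#'   (same features).
#' @param mode `"significant"` (default: both contrasts must pass) or
#'   `"direction_only"`.
#' @return character vector of restored feature ids.
#' @export
restored_features <- function(diff_disease, diff_treatment,
                              mode = c("significant", "direction_only")) {
  mode <- match.arg(mode)
  if (!setequal(diff_disease$feature, diff_treatment$feature))
    stop("the two screens must cover the same features")
  dt <- diff_treatment[match(diff_disease$feature, diff_treatment$feature), ]
  opposite <- sign(diff_disease$log2fc) * sign(dt$log2fc) < 0  # excludes 0
  keep <- diff_disease$pass & opposite &
    (if (mode == "significant") dt$pass else TRUE)
  diff_disease$feature[keep]
}

#' Taxon-metabolite Spearman association matrix
#'
#' Pairwise Spearman rank correlation (tie-corrected, via ranks) between
#' every taxon and every metabolite over shared samples, with two-sided
#' p-values from the t approximation and optional multiplicity adjustment
#' across all pairs. Constant features yield undefined correlations,
#' reported as NA with a warning.
#'
#' @param taxa numeric matrix, taxa x samples.
#' @param metabolites numeric matrix, metabolites x samples (same sample
#'   columns).
#' @param adjust p-adjustment method for [stats::p.adjust()] (default
#'   `"BH"`; `"none"` to skip).
#' @return list of class `association_matrix` with `rho`, `p`, `p_adj`
#'   (taxa x metabolites matrices).
#' @export
spearman_matrix <- function(taxa, metabolites, adjust = "BH") {
  taxa <- as.matrix(taxa); metabolites <- as.matrix(metabolites)
  shared <- intersect(colnames(taxa), colnames(metabolites))
  if (length(shared) < 4) stop("need at least 4 shared samples")
  taxa <- taxa[, shared, drop = FALSE]
  metabolites <- metabolites[, shared, drop = FALSE]
  n <- length(shared)
  const_t <- apply(taxa, 1, function(v) length(unique(v)) == 1)
  const_m <- apply(metabolites, 1, function(v) length(unique(v)) == 1)
  if (any(const_t) || any(const_m))
    warning("constant feature(s); their correlations are undefined (NA)")
  rho <- suppressWarnings(
    stats::cor(t(taxa), t(metabolites), method = "spearman"))
  rho[const_t, ] <- NA_real_
  rho[, const_m] <- NA_real_
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  p[abs(rho) == 1] <- 0
  p_adj <- matrix(stats::p.adjust(p, method = adjust), nrow(p), ncol(p),
                  dimnames = dimnames(p))
  structure(list(rho = rho, p = p, p_adj = p_adj, n = n),
            class = "association_matrix")
}

#' @export
print.association_matrix <- function(x, ...) {
  cat(sprintf("Spearman association matrix: %d taxa x %d metabolites (n = %d)\n",
              nrow(x$rho), ncol(x$rho), x$n))
  print(round(x$rho, 3))
  invisible(x)
}
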