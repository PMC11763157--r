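#' Define a synthetic recovery study
#'
#' Describes a five-group (sham / model / monotherapy arms / combination)
#' expression study with planted disease dysregulation and planted per-arm
#' recovery. The planted quantities are exact at the group-mean level;
#' multiplicative lognormal noise with the stated coefficient of variation is
#' layered on top, so at `noise_cv = 0` every downstream estimator recovers
#' the planted values exactly.
#'
#' The per-arm recovery profile is given either as sampling ranges
#' (`eor_profile`) or as an explicit planted EoR matrix (`planted_eor`,
#' dysregulated genes x arms, percent units, values <= 100). Default profile
#' ranges keep planted EoR well away from the recovered/not-recovered
#' boundary at 0 so that classification is unambiguous at moderate noise.
#'
#' @param arms character vector of treatment-arm group names (the last is
#'   conventionally the combination, but nothing depends on that).
#' @param replicates samples per group (>= 2).
#' @param n_genes number of genes in the transcriptome universe.
#' @param n_disease_genes number of genes belonging to the disease reference
#'   set (<= n_genes).
#' @param frac_dysregulated proportion of disease genes perturbed in the
#'   model group.
#' @param eor_profile named list per arm with `frac_recovered`,
#'   `recovered_range` (default c(25, 95)) and `nonrecovered_range`
#'   (default c(-95, -25)); ignored when `planted_eor` is given.
#' @param planted_eor optional numeric matrix of planted EoR values, one row
#'   per dysregulated gene (rownames = gene ids, which must exist in the
#'   universe; or NULL rownames to use a seeded sample), one column per arm.
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   noise (>= 0).
#' @param seed master integer seed.
#' @param genes optional explicit gene ids (length `n_genes`).
#' @return object of class `study_design`.
#' @export
study_design <- function(arms = c("cf", "bbp", "combination"),
                         replicates = 6,
                         n_genes = 2000,
                         n_disease_genes = 400,
                         frac_dysregulated = 0.6,
                         eor_profile = NULL,
                         planted_eor = NULL,
                         noise_cv = 0.1,
                         seed = 1,
                         genes = NULL) {
  if (anyDuplicated(c("sham", "model", arms)))
    stop("group names must be unique (and distinct from 'sham'/'model')")
  if (replicates < 2) stop("replicates must be >= 2")
  if (n_genes < 1 || n_disease_genes < 1 || n_disease_genes > n_genes)
    stop("need 1 <= n_disease_genes <= n_genes")
  if (frac_dysregulated < 0 || frac_dysregulated > 1)
    stop("frac_dysregulated must lie in [0, 1]")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (!is.null(genes)) {
    if (length(genes) != n_genes) stop("genes must have length n_genes")
  } else {
    genes <- sprintf("G%05d", seq_len(n_genes))
  }
  if (is.null(eor_profile) && is.null(planted_eor)) {
    eor_profile <- stats::setNames(lapply(arms, function(a) list(
      frac_recovered = 0.6,
      recovered_range = c(25, 95),
      nonrecovered_range = c(-95, -25)
    )), arms)
  }
  if (!is.null(planted_eor)) {
    planted_eor <- as.matrix(planted_eor)
    if (is.null(colnames(planted_eor))) colnames(planted_eor) <- arms
    if (!all(colnames(planted_eor) %in% arms))
      stop("planted_eor columns must be named after arms")
    if (any(planted_eor > 100)) stop("planted EoR values must be <= 100")
    if (nrow(planted_eor) > n_disease_genes)
      stop("planted_eor has more rows than n_disease_genes")
  }
  structure(list(arms = arms, replicates = replicates, n_genes = n_genes,
                 n_disease_genes = n_disease_genes,
                 frac_dysregulated = frac_dysregulated,
                 eor_profile = eor_profile, planted_eor = planted_eor,
                 noise_cv = noise_cv, seed = seed, genes = genes),
            class = "study_design")
}

# lognormal multiplier with unit mean and the given coefficient of variation
lnorm_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  exp(stats::rnorm(n, mean = -s2 / 2, sd = sqrt(s2)))
}

#' Generate a synthetic expression study with planted recovery ground truth
#'
#' Group means realize the planted fold changes exactly before noise. For a
#' dysregulated gene with disease fold change d = sham/model and planted EoR
#' e for an arm, the treatment fold change is obtained by inverting the EoR
#' formula: the normalized ratio r = fc_arm/fc_disease satisfies
#' |1 - r| = (100 - e)/100, giving two branches r = e/100 and r = 2 - e/100.
#' The generator picks the branch on the same side as the natural recovery
#' path from "no treatment effect" (r = 1/d) toward complete recovery
#' (r = 1), falling back to the other branch when the preferred one would
#' give a non-positive ratio; the branch used is recorded in the ground
#' truth. Either branch reproduces e exactly under the EoR formula.
#'
#' @param design a [study_design()].
#' @return list of class `expression_study` with elements `expression`
#'   (genes x samples matrix), `samples` (data.frame: sample, group) and
#'   `truth` (planted ground truth: disease genes, dysregulated genes, base
#'   means, disease fold changes, planted EoR matrix, planted recovery
#'   flags, branch matrix, and planted arm fold changes).
#' @export
gen_expression_study <- function(design) {
  stopifnot(inherits(design, "study_design"))
  d <- design
  set.seed(split_seed(d$seed, "expression"))
  genes <- d$genes
  disease_genes <- sort(sample(genes, d$n_disease_genes))

  if (!is.null(d$planted_eor)) {
    if (!is.null(rownames(d$planted_eor))) {
      dysreg <- rownames(d$planted_eor)
      if (!all(dysreg %in% genes))
        stop("planted_eor rownames must be gene ids of the universe")
      disease_genes <- sort(unique(c(
        dysreg,
        sample(setdiff(genes, dysreg),
               max(0, d$n_disease_genes - length(dysreg)))
      )))
      planted <- d$planted_eor
    } else {
      dysreg <- sort(sample(disease_genes, nrow(d$planted_eor)))
      planted <- d$planted_eor
      rownames(planted) <- dysreg
    }
  } else {
    n_dys <- round(d$frac_dysregulated * d$n_disease_genes)
    dysreg <- sort(sample(disease_genes, n_dys))
    planted <- matrix(NA_real_, n_dys, length(d$arms),
                      dimnames = list(dysreg, d$arms))
    for (a in d$arms) {
      prof <- d$eor_profile[[a]]
      if (is.null(prof)) stop("eor_profile missing for arm: ", a)
      rec_rng <- if (is.null(prof$recovered_range)) c(25, 95)
                 else prof$recovered_range
      non_rng <- if (is.null(prof$nonrecovered_range)) c(-95, -25)
                 else prof$nonrecovered_range
      n_rec <- round(prof$frac_recovered * n_dys)
      rec <- rep(FALSE, n_dys)
      rec[sample.int(n_dys, n_rec)] <- TRUE
      planted[rec, a] <- stats::runif(n_rec, rec_rng[1], rec_rng[2])
      planted[!rec, a] <- stats::runif(n_dys - n_rec, non_rng[1], non_rng[2])
    }
  }
  planted <- planted[, d$arms, drop = FALSE]

  n <- length(genes)
  base_mean <- stats::setNames(exp(stats::rnorm(n, log(100), 1)), genes)
  fc_disease <- stats::setNames(rep(1, n), genes)
  mag <- stats::runif(length(dysreg), 1, 3)
  sign <- sample(c(-1, 1), length(dysreg), replace = TRUE)
  fc_disease[dysreg] <- 2^(sign * mag)

  # invert EoR to a normalized ratio r = fc_arm / fc_disease per gene x arm
  arms <- d$arms
  ratio <- matrix(1, n, length(arms), dimnames = list(genes, arms))
  branch <- matrix(NA_character_, nrow(planted), ncol(planted),
                   dimnames = dimnames(planted))
  for (a in arms) {
    e <- planted[, a]
    dg <- fc_disease[rownames(planted)]
    lower <- e / 100        # r below 1
    upper <- 2 - e / 100    # r above 1
    prefer_lower <- dg > 1  # no-effect point r = 1/d sits below 1
    r <- ifelse(prefer_lower, lower, upper)
    use_other <- r <= 0
    r[use_other] <- ifelse(prefer_lower, upper, lower)[use_other]
    if (any(r <= 0)) stop("planted EoR not realizable with positive ratios")
    branch[, a] <- ifelse(r <= 1, "lower", "upper")
    ratio[rownames(planted), a] <- r
  }

  groups <- c("sham", "model", arms)
  samples <- data.frame(
    sample = unlist(lapply(groups, function(g)
      paste0(g, "_", seq_len(d$replicates)))),
    group = rep(groups, each = d$replicates),
    stringsAsFactors = FALSE
  )
  means <- matrix(0, n, length(groups), dimnames = list(genes, groups))
  means[, "sham"] <- base_mean
  means[, "model"] <- base_mean / fc_disease
  for (a in arms) means[, a] <- base_mean * ratio[, a]

  expr <- means[, samples$group, drop = FALSE]
  colnames(expr) <- samples$sample
  expr <- expr * matrix(lnorm_noise(length(expr), d$noise_cv), nrow = n)

  recovered <- planted > 0
  truth <- list(
    genes = genes,
    disease_genes = disease_genes,
    dysregulated = rownames(planted),
    base_mean = base_mean,
    fc_disease = fc_disease,
    planted_eor = planted,
    planted_recovered = recovered,
    branch = branch,
    planted_fc_arm = ratio * fc_disease
  )
  structure(list(expression = expr, samples = samples, truth = truth,
                 design = d),
            class = "expression_study")
}

#' Generate a random PPI edge table (Erdős–Rényi with target mean degree)
#'
#' Simple undirected graph: no self-loops, no duplicate pairs. Each of the
#' n(n-1)/2 unordered pairs is an edge independently with probability
#' `mean_degree / (n - 1)`; edge confidences are uniform on [0, 1].
#' Degree-distribution realism (hubs, scale-free tails) is deliberately not
#' modelled.
#'
#' @param genes character vector of node ids (>= 2).
#' @param mean_degree expected mean degree (0 <= mean_degree <= n - 1; at
#'   the upper bound the graph is complete).
#' @param seed integer seed.
#' @return data.frame with columns `gene_a`, `gene_b`, `confidence`.
#' @export
gen_ppi <- function(genes, mean_degree, seed = 1) {
  n <- length(genes)
  if (n < 2) stop("need at least 2 genes")
  if (mean_degree < 0 || mean_degree > n - 1)
    stop("mean_degree must lie in [0, n - 1]")
  set.seed(split_seed(seed, "ppi"))
  p <- mean_degree / (n - 1)
  ia <- integer(0); ib <- integer(0)
  if (p > 0) {
    for (i in seq_len(n - 1)) {
      j <- which(stats::runif(n - i) < p) + i
      if (length(j)) {
        ia <- c(ia, rep.int(i, length(j)))
        ib <- c(ib, j)
      }
    }
  }
  data.frame(gene_a = genes[ia], gene_b = genes[ib],
             confidence = stats::runif(length(ia)),
             stringsAsFactors = FALSE)
}

#' Generate plate-assay readouts with planted treatment effects
#'
#' Emulates absorbance readouts of an induced assay: the model group sits at
#' `model_mean`, the control group at `control_mean`, and each treatment
#' group at `model_mean + E * (control_mean - model_mean)` for its planted
#' effect E, so [normalize_effect()] recovers E exactly at zero noise.
#' Gaussian noise with standard deviation `noise_sd` is added per well.
#'
#' @param true_effects named numeric vector of planted effects in [0, 1]
#'   (names become group labels, e.g. c(cf = 0.3, bbp = 0.4,
#'   combination = 0.58)).
#' @param n_replicates wells per group (>= 2).
#' @param noise_sd per-well Gaussian noise standard deviation (>= 0).
#' @param seed integer seed.
#' @param control_mean,model_mean anchor group means (must differ).
#' @return data.frame with columns `well`, `group`, `value`.
#' @export
gen_assay <- function(true_effects, n_replicates = 6, noise_sd = 0.02,
                      seed = 1, control_mean = 0.2, model_mean = 1.0) {
  if (any(true_effects < 0 | true_effects > 1))
    stop("all true effects must lie in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_replicates < 2) stop("need >= 2 replicates per group")
  if (control_mean == model_mean) stop("control and model means must differ")
  if (is.null(names(true_effects)) || any(!nzchar(names(true_effects))))
    stop("true_effects must be named by group")
  set.seed(split_seed(seed, "assay"))
  groups <- c("control", "model", names(true_effects))
  means <- c(control_mean, model_mean,
             model_mean + true_effects * (control_mean - model_mean))
  out <- data.frame(
    well = sprintf("W%03d", seq_len(length(groups) * n_replicates)),
    group = rep(groups, each = n_replicates),
    value = rep(means, each = n_replicates) +
      stats::rnorm(length(groups) * n_replicates, 0, noise_sd),
    stringsAsFactors = FALSE
  )
  out
}

#' Generate paired taxon and metabolite tables with planted Spearman structure
#'
#' Uses a Gaussian copula: a latent multivariate normal sample whose
#' taxon-metabolite cross-correlations are `2 * sin(pi * rho / 6)` — the
#' Pearson latent correlation whose induced Spearman correlation equals the
#' planted `rho` — is pushed through monotone lognormal quantile transforms.
#' Because the transforms are strictly monotone per feature, the planted
#' values are Spearman (rank) correlations, not Pearson, and a planted rho
#' of +/-1 is reproduced exactly at any sample size. Within-block (taxon-
#' taxon, metabolite-metabolite) latent correlations are zero.
#'
#' @param n_taxa,n_metabolites numbers of features.
#' @param n_samples samples per group (> 0).
#' @param rho planted Spearman matrix, n_taxa x n_metabolites, entries in
#'   [-1, 1]; the implied joint correlation matrix must be positive
#'   semi-definite (with zero within-block correlation this caps each
#'   feature's latent cross-correlation vector at norm 1).
#' @param seed integer seed.
#' @param groups character vector of group labels (default a single group);
#'   the copula structure is common to all groups.
#' @return list of class `paired_omics`: `taxa` (matrix taxa x samples),
#'   `metabolites` (matrix features x samples), `samples` (data.frame),
#'   `scores` (metabolite annotation scores) and `truth` (planted rho).
#' @export
gen_paired_omics <- function(n_taxa, n_metabolites, n_samples, rho, seed = 1,
                             groups = "all") {
  if (n_samples <= 0) stop("n_samples must be positive")
  rho <- as.matrix(rho)
  if (nrow(rho) != n_taxa || ncol(rho) != n_metabolites)
    stop("rho must be n_taxa x n_metabolites")
  if (any(abs(rho) > 1)) stop("planted rho entries must lie in [-1, 1]")
  set.seed(split_seed(seed, "paired_omics"))
  latent <- 2 * sin(pi * rho / 6)
  p <- n_taxa + n_metabolites
  sigma <- diag(p)
  sigma[seq_len(n_taxa), n_taxa + seq_len(n_metabolites)] <- latent
  sigma[n_taxa + seq_len(n_metabolites), seq_len(n_taxa)] <- t(latent)
  es <- eigen(sigma, symmetric = TRUE)
  if (min(es$values) < -1e-8)
    stop("planted rho matrix is not jointly realizable ",
         "(implied correlation matrix is not positive semi-definite); ",
         "each feature's vector of latent cross-correlations must have ",
         "norm <= 1 when within-block correlations are zero")
  sqrt_sigma <- es$vectors %*% (sqrt(pmax(es$values, 0)) * t(es$vectors))
  ntot <- n_samples * length(groups)
  z <- matrix(stats::rnorm(ntot * p), ntot, p) %*% sqrt_sigma
  u <- stats::pnorm(z)
  taxa_mean <- stats::runif(n_taxa, log(10), log(1000))
  met_mean <- stats::runif(n_metabolites, log(10), log(1000))
  taxa <- t(stats::qlnorm(u[, seq_len(n_taxa), drop = FALSE],
                          meanlog = rep(taxa_mean, each = ntot), sdlog = 1))
  mets <- t(stats::qlnorm(u[, n_taxa + seq_len(n_metabolites), drop = FALSE],
                          meanlog = rep(met_mean, each = ntot), sdlog = 1))
  rownames(taxa) <- sprintf("taxon_%02d", seq_len(n_taxa))
  rownames(mets) <- sprintf("met_%03d", seq_len(n_metabolites))
  samples <- data.frame(
    sample = sprintf("S%03d", seq_len(ntot)),
    group = rep(groups, each = n_samples),
    stringsAsFactors = FALSE
  )
  colnames(taxa) <- colnames(mets) <- samples$sample
  rownames(rho) <- rownames(taxa); colnames(rho) <- rownames(mets)
  structure(list(taxa = taxa, metabolites = mets, samples = samples,
                 scores = stats::setNames(
                   stats::runif(n_metabolites, 30, 60), rownames(mets)),
                 truth = list(rho = rho)),
            class = "paired_omics")
}

#' Generate a metabolite screening study with planted restored features
#'
#' Builds a metabolite abundance table over sham / model / treatment groups
#' with four planted feature classes: `restored` (shifted by disease,
#' shifted back to the sham level by treatment), `disease_only` (shifted by
#' disease, untouched by treatment), `same_sign` (shifted by disease and
#' pushed further in the same direction by treatment) and `null` (no group
#' differences). Planted shifts are `lfc` log2 units with random sign;
#' non-null features carry annotation scores above the conventional passing
#' threshold, null features mixed scores. Noise is multiplicative lognormal.
#'
#' @param n_restored,n_disease_only,n_same_sign,n_null feature counts per
#'   class.
#' @param replicates samples per group (>= 2).
#' @param lfc planted absolute log2 fold change of the disease shift.
#' @param noise_cv lognormal coefficient of variation (> 0 so t-tests are
#'   well-defined).
#' @param seed integer seed.
#' @param treatment treatment group name.
#' @return list of class `metabolite_study`: `abundance` (features x
#'   samples), `samples`, `scores`, `truth` (feature classes and planted
#'   shifts).
#' @export
gen_metabolite_study <- function(n_restored = 70, n_disease_only = 40,
                                 n_same_sign = 20, n_null = 200,
                                 replicates = 6, lfc = 2, noise_cv = 0.1,
                                 seed = 1, treatment = "combination") {
  if (replicates < 2) stop("replicates must be >= 2")
  if (noise_cv <= 0) stop("noise_cv must be positive")
  set.seed(split_seed(seed, "metabolites"))
  classes <- rep(c("restored", "disease_only", "same_sign", "null"),
                 c(n_restored, n_disease_only, n_same_sign, n_null))
  nfeat <- length(classes)
  feats <- sprintf("met_%04d", seq_len(nfeat))
  base <- exp(stats::rnorm(nfeat, log(500), 1))
  sgn <- sample(c(-1, 1), nfeat, replace = TRUE)
  m_sham <- base
  m_model <- base
  m_treat <- base
  dis <- classes != "null"
  m_model[dis] <- base[dis] * 2^(sgn[dis] * lfc)
  m_treat[classes == "restored"] <- base[classes == "restored"]
  m_treat[classes == "disease_only"] <- m_model[classes == "disease_only"]
  ss <- classes == "same_sign"
  m_treat[ss] <- base[ss] * 2^(sgn[ss] * lfc * 1.5)
  groups <- c("sham", "model", treatment)
  samples <- data.frame(
    sample = unlist(lapply(groups, function(g)
      paste0(g, "_", seq_len(replicates)))),
    group = rep(groups, each = replicates),
    stringsAsFactors = FALSE
  )
  means <- cbind(sham = m_sham, model = m_model, m_treat)
  colnames(means)[3] <- treatment
  ab <- means[, samples$group, drop = FALSE]
  dimnames(ab) <- list(feats, samples$sample)
  ab <- ab * matrix(lnorm_noise(length(ab), noise_cv), nrow = nfeat)
  scores <- stats::setNames(numeric(nfeat), feats)
  scores[dis] <- stats::runif(sum(dis), 45, 60)
  scores[!dis] <- stats::runif(sum(!dis), 20, 60)
  structure(list(abundance = ab, samples = samples, scores = scores,
                 truth = list(class = stats::setNames(classes, feats),
                              sign = stats::setNames(sgn, feats),
                              lfc = lfc)),
            class = "metabolite_study")
}
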