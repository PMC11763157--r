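test_that("differential_screen agrees with stats::t.test feature by feature", {
  set.seed(23)
  ab <- matrix(rlnorm(8 * 10, log(100), 0.5), nrow = 8,
               dimnames = list(sprintf("f%d", 1:8), sprintf("s%d", 1:10)))
  samples <- data.frame(sample = colnames(ab),
                        group = rep(c("model", "sham"), each = 5))
  res <- differential_screen(ab, samples, "model", "sham",
                             scores = setNames(rep(50, 8), rownames(ab)))
  for (i in 1:8) {
    ref <- t.test(ab[i, 1:5], ab[i, 6:10])
    expect_equal(res$p[i], ref$p.value, tolerance = 1e-12)
  }
})

test_that("identical groups produce no passing features", {
  ab <- matrix(rep(c(5, 7, 9, 11), each = 8), nrow = 4, byrow = TRUE)
  ab <- ab + matrix(rep(c(0, 0.1, -0.1, 0.2, 0, 0.1, -0.1, 0.2), 4),
                    nrow = 4, byrow = TRUE)
  dimnames(ab) <- list(paste0("f", 1:4), paste0("s", 1:8))
  samples <- data.frame(sample = colnames(ab),
                        group = rep(c("a", "b"), each = 4))
  res <- differential_screen(ab, samples, "a", "b",
                             scores = setNames(rep(50, 4), rownames(ab)))
  expect_false(any(res$pass))
  expect_equal(res$log2fc, rep(0, 4), tolerance = 1e-12)
})

test_that("a strong planted shift passes all three gates", {
  ms <- gen_metabolite_study(n_restored = 5, n_disease_only = 0,
                             n_same_sign = 0, n_null = 0, replicates = 10,
                             lfc = 2, noise_cv = 0.1, seed = 3)
  res <- differential_screen(ms$abundance, ms$samples, "model", "sham",
                             scores = ms$scores)
  expect_true(all(res$pass))
  expect_true(all(abs(abs(res$log2fc) - 2) < 0.5))
})

test_that("zero within-group variance triggers the exact-equality rule", {
  ab <- rbind(f1 = c(3, 3, 3, 3), f2 = c(3, 3, 4, 4))
  colnames(ab) <- paste0("s", 1:4)
  samples <- data.frame(sample = colnames(ab),
                        group = rep(c("a", "b"), each = 2))
  expect_warning(res <- differential_screen(ab, samples, "a", "b",
                                            scores = c(f1 = 50, f2 = 50)),
                 "zero within-group variance")
  expect_equal(res$p[1], 1)   # equal means
  expect_equal(res$p[2], 0)   # unequal means, flagged degenerate
  expect_true(res$degenerate[2])
})

test_that("disabling a gate never shrinks the passing set", {
  ms <- gen_metabolite_study(seed = 29)
  base <- differential_screen(ms$abundance, ms$samples, "model", "sham",
                              scores = ms$scores)
  no_score <- differential_screen(ms$abundance, ms$samples, "model", "sham",
                                  scores = ms$scores, score_thresh = -Inf)
  no_lfc <- differential_screen(ms$abundance, ms$samples, "model", "sham",
                                scores = ms$scores, lfc_thresh = -Inf)
  no_p <- differential_screen(ms$abundance, ms$samples, "model", "sham",
                              scores = ms$scores, p_thresh = 1)
  expect_true(all(base$feature[base$pass] %in% no_score$feature[no_score$pass]))
  expect_true(all(base$feature[base$pass] %in% no_lfc$feature[no_lfc$pass]))
  expect_true(all(base$feature[base$pass] %in% no_p$feature[no_p$pass]))
})

test_that("restored_features requires opposite signs and containment in the disease screen", {
  dd <- data.frame(feature = c("a", "b", "c", "d"),
                   p = c(0.01, 0.01, 0.01, 0.5),
                   log2fc = c(-1, -1, 1, -1),
                   score = 50, pass = c(TRUE, TRUE, TRUE, FALSE))
  dt <- data.frame(feature = c("a", "b", "c", "d"),
                   p = c(0.01, 0.01, 0.01, 0.01),
                   log2fc = c(0.5, -0.5, -0.8, 0.5),
                   score = 50, pass = TRUE)
  res <- restored_features(dd, dt)
  expect_setequal(res, c("a", "c"))   # b same sign, d fails disease screen
  expect_true(all(res %in% dd$feature[dd$pass]))
  # direction-only mode ignores treatment significance
  dt2 <- dt; dt2$pass <- FALSE
  expect_length(restored_features(dd, dt2), 0)
  expect_setequal(restored_features(dd, dt2, mode = "direction_only"),
                  c("a", "c"))
  # zero treatment fold change is excluded
  dt3 <- dt; dt3$log2fc[1] <- 0
  expect_setequal(restored_features(dd, dt3), "c")
  expect_error(restored_features(dd, dt[1:3, ]), "same features")
})

test_that("the planted restored set is recovered from a synthetic study", {
  ms <- gen_metabolite_study(n_restored = 70, n_disease_only = 40,
                             n_same_sign = 20, n_null = 200, seed = 1)
  dd <- differential_screen(ms$abundance, ms$samples, "model", "sham",
                            scores = ms$scores)
  dt <- differential_screen(ms$abundance, ms$samples, "combination", "model",
                            scores = ms$scores)
  res <- restored_features(dd, dt)
  planted <- names(ms$truth$class)[ms$truth$class == "restored"]
  expect_true(all(planted %in% res))           # full power on planted features
  expect_lte(length(setdiff(res, planted)), 3) # rare screen false positives
})

test_that("spearman_matrix matches the brute-force rank oracle exactly", {
  set.seed(31)
  taxa <- matrix(rlnorm(4 * 12), nrow = 4,
                 dimnames = list(paste0("t", 1:4), paste0("s", 1:12)))
  mets <- matrix(rlnorm(4 * 12), nrow = 4,
                 dimnames = list(paste0("m", 1:4), paste0("s", 1:12)))
  mets[2, ] <- rep(c(1, 2, 3), 4)  # ties exercise the correction
  res <- spearman_matrix(taxa, mets, adjust = "BH")
  for (i in 1:4) for (j in 1:4) {
    expect_equal(res$rho[i, j], spearman_oracle(taxa[i, ], mets[j, ]),
                 tolerance = 1e-12)
  }
  expect_true(all(res$rho >= -1 & res$rho <= 1))
  expect_equal(dim(res$rho), c(4, 4))
  expect_equal(res$p_adj, matrix(p.adjust(res$p, "BH"), 4, 4,
                                 dimnames = dimnames(res$p)))
})

test_that("spearman is invariant under strictly monotone transforms and signs reverse", {
  set.seed(33)
  x <- rlnorm(20); y <- x^1.7 + 0  # monotone transform of x
  taxa <- rbind(t1 = x)
  mets <- rbind(m1 = y, m2 = max(x) - x + 1)
  colnames(taxa) <- colnames(mets) <- paste0("s", 1:20)
  res <- spearman_matrix(taxa, mets, adjust = "none")
  expect_equal(res$rho["t1", "m1"], 1)
  expect_equal(res$rho["t1", "m2"], -1)
  expect_equal(res$p["t1", "m1"], 0)
  # exp() transform of the taxon leaves every rho unchanged
  res2 <- spearman_matrix(exp(taxa), mets, adjust = "none")
  expect_equal(res$rho, res2$rho, tolerance = 1e-12)
})

test_that("spearman_matrix handles constant features and few samples", {
  taxa <- rbind(t1 = c(1, 2, 3, 4, 5), t2 = rep(2, 5))
  mets <- rbind(m1 = c(5, 3, 4, 1, 2))
  colnames(taxa) <- colnames(mets) <- paste0("s", 1:5)
  expect_warning(res <- spearman_matrix(taxa, mets), "constant")
  expect_true(is.na(res$rho["t2", "m1"]))
  expect_false(is.na(res$rho["t1", "m1"]))
  expect_error(spearman_matrix(taxa[, 1:3], mets[, 1:3, drop = FALSE]),
               "at least 4")
})
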