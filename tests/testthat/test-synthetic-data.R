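test_that("study_design validates its fields", {
  expect_error(study_design(replicates = 1), ">= 2")
  expect_error(study_design(n_genes = 10, n_disease_genes = 20), "<=")
  expect_error(study_design(frac_dysregulated = 1.2), "\\[0, 1\\]")
  expect_error(study_design(noise_cv = -0.1), ">= 0")
  expect_error(study_design(arms = c("a", "a")), "unique")
  expect_error(study_design(arms = c("sham", "x")), "unique")
  expect_error(study_design(planted_eor = matrix(150, 1, 3,
    dimnames = list(NULL, c("cf", "bbp", "combination")))), "<= 100")
})

test_that("identical seeds give bit-identical synthetic outputs", {
  d <- study_design(n_genes = 100, n_disease_genes = 30, replicates = 3,
                    noise_cv = 0.2, seed = 77)
  s1 <- gen_expression_study(d)
  s2 <- gen_expression_study(d)
  expect_identical(s1$expression, s2$expression)
  expect_identical(s1$truth, s2$truth)
  expect_identical(gen_ppi(letters, 3, seed = 5), gen_ppi(letters, 3, seed = 5))
  expect_identical(gen_assay(c(a = 0.5), seed = 9, noise_sd = 0.1),
                   gen_assay(c(a = 0.5), seed = 9, noise_sd = 0.1))
  p1 <- gen_paired_omics(3, 3, 20, diag(0.5, 3), seed = 4)
  p2 <- gen_paired_omics(3, 3, 20, diag(0.5, 3), seed = 4)
  expect_identical(p1$taxa, p2$taxa)
  expect_identical(p1$metabolites, p2$metabolites)
  m1 <- gen_metabolite_study(seed = 13)
  m2 <- gen_metabolite_study(seed = 13)
  expect_identical(m1$abundance, m2$abundance)
  # different stage labels decorrelate child seeds
  expect_false(split_seed(1, "expression") == split_seed(1, "ppi"))
  expect_identical(split_seed(123, "x"), split_seed(123, "x"))
})

test_that("zero-noise studies realize planted fold changes and EoR exactly", {
  d <- study_design(n_genes = 200, n_disease_genes = 80, replicates = 3,
                    frac_dysregulated = 0.5, noise_cv = 0, seed = 42)
  st <- gen_expression_study(d)
  fc <- compute_fold_changes(st$expression, st$samples, arms = d$arms,
                             pseudo_count = 0)
  rownames(fc) <- fc$gene
  dys <- st$truth$dysregulated
  expect_equal(fc[dys, "fc_disease"],
               unname(st$truth$fc_disease[dys]), tolerance = 1e-9)
  tab <- eor_table(fc, arms = d$arms)
  rownames(tab) <- tab$gene
  for (a in d$arms) {
    expect_equal(tab[dys, paste0("eor_", a)],
                 unname(st$truth$planted_eor[dys, a]), tolerance = 1e-9)
    expect_equal(tab[dys, paste0("recovered_", a)],
                 unname(st$truth$planted_recovered[dys, a]))
  }
  # non-dysregulated genes are unmoved in every contrast
  quiet <- setdiff(st$truth$genes, dys)
  expect_equal(fc[quiet, "fc_disease"], rep(1, length(quiet)),
               tolerance = 1e-9)
})

test_that("planted recovery counts are reproduced exactly at zero noise", {
  planted <- matrix(c(rep(60, 40), rep(-40, 24)), ncol = 1,
                    dimnames = list(NULL, "combination"))
  d <- study_design(arms = "combination", n_genes = 120,
                    n_disease_genes = 64, planted_eor = planted,
                    noise_cv = 0, replicates = 2, seed = 5)
  st <- gen_expression_study(d)
  fc <- compute_fold_changes(st$expression, st$samples, arms = "combination",
                             pseudo_count = 0)
  tab <- eor_table(fc[fc$gene %in% st$truth$dysregulated, ])
  expect_equal(recovery_rate(tab, "combination")$count, 40)
})

test_that("EoR inversion uses the recovery-path branch and records it", {
  planted <- matrix(c(80, -20), ncol = 1, dimnames = list(NULL, "tx"))
  d <- study_design(arms = "tx", n_genes = 10, n_disease_genes = 2,
                    planted_eor = planted, noise_cv = 0, replicates = 2,
                    seed = 31)
  st <- gen_expression_study(d)
  dys <- st$truth$dysregulated
  r <- st$truth$planted_fc_arm[dys, "tx"] / st$truth$fc_disease[dys]
  dgt1 <- st$truth$fc_disease[dys] > 1
  # positive planted EoR sits on the same side as the no-effect point 1/d
  pos <- st$truth$planted_eor[dys, "tx"] > 0
  expect_true(all(r[dgt1 & pos] < 1))
  expect_true(all(r[!dgt1] > 1))
  expect_true(all(r > 0))
  expect_equal(unname(st$truth$branch[dys, "tx"]),
               unname(ifelse(r <= 1, "lower", "upper")))
})

test_that("gen_ppi produces a simple graph with the requested mean degree", {
  e <- gen_ppi(c("A", "B"), 1, seed = 1)
  expect_equal(nrow(e), 1)
  expect_equal(nrow(gen_ppi(letters, 0, seed = 1)), 0)
  expect_error(gen_ppi("A", 1), "at least 2")
  expect_error(gen_ppi(letters[1:5], 4.5), "n - 1")
  ids <- sprintf("g%03d", 1:100)
  e <- gen_ppi(ids, 6, seed = 17)
  expect_true(all(e$gene_a != e$gene_b))
  key <- paste(pmin(e$gene_a, e$gene_b), pmax(e$gene_a, e$gene_b))
  expect_false(anyDuplicated(key) > 0)
  expect_true(all(e$confidence >= 0 & e$confidence <= 1))
  realized <- 2 * nrow(e) / length(ids)
  expect_lt(abs(realized - 6), 1)
})

test_that("gen_assay anchors map to effects 0 and 1 at zero noise", {
  ro <- gen_assay(c(tx = 0.37), n_replicates = 3, noise_sd = 0, seed = 2)
  expect_equal(normalize_effect(ro, "control")$E, 1)
  expect_equal(normalize_effect(ro, "model")$E, 0)
  expect_equal(normalize_effect(ro, "tx")$E, 0.37, tolerance = 1e-12)
  expect_error(gen_assay(c(tx = 1.2)), "\\[0, 1\\]")
  expect_error(gen_assay(c(tx = 0.5), noise_sd = -1), ">= 0")
  expect_error(gen_assay(c(0.5)), "named")
})

test_that("paired omics copula reproduces planted Spearman structure", {
  # perfect rank agreement is exact at any n
  p <- gen_paired_omics(1, 1, 25, matrix(1, 1, 1), seed = 6)
  expect_equal(cor(p$taxa[1, ], p$metabolites[1, ], method = "spearman"), 1)
  pneg <- gen_paired_omics(1, 1, 25, matrix(-1, 1, 1), seed = 6)
  expect_equal(cor(pneg$taxa[1, ], pneg$metabolites[1, ], method = "spearman"),
               -1)
  # a strong planted correlation is recovered within sampling error
  p8 <- gen_paired_omics(1, 1, 500, matrix(-0.8, 1, 1), seed = 8)
  est <- cor(p8$taxa[1, ], p8$metabolites[1, ], method = "spearman")
  expect_lt(abs(est - (-0.8)), 0.1)
  # a null pair stays near zero
  p0 <- gen_paired_omics(1, 1, 200, matrix(0, 1, 1), seed = 9)
  expect_lt(abs(cor(p0$taxa[1, ], p0$metabolites[1, ], method = "spearman")),
            0.2)
  expect_error(gen_paired_omics(1, 1, 0, matrix(0, 1, 1)), "positive")
  expect_error(gen_paired_omics(1, 1, 10, matrix(2, 1, 1)), "\\[-1, 1\\]")
  expect_error(gen_paired_omics(2, 2, 10, matrix(0.9, 2, 2)),
               "not jointly realizable")
})

test_that("metabolite study plants the requested feature classes", {
  ms <- gen_metabolite_study(n_restored = 10, n_disease_only = 5,
                             n_same_sign = 3, n_null = 20, replicates = 4,
                             seed = 19)
  expect_equal(sum(ms$truth$class == "restored"), 10)
  expect_equal(dim(ms$abundance), c(38, 12))
  expect_true(all(ms$scores[ms$truth$class != "null"] >= 38.1))
  expect_error(gen_metabolite_study(noise_cv = 0), "positive")
})

test_that("demo fixtures mirror the planted headline counts", {
  m <- demo_recovery_matrix()
  expect_equal(nrow(m), 1447)
  expect_equal(colSums(m > 0), c(combination = 902, cf = 804, bbp = 437))
  net <- demo_network_inputs(seed = 3)
  expect_length(net$universe, 32545)
  expect_length(net$reference, 1641)
  expect_length(intersect(net$universe, net$reference), 1539)
  expect_length(net$isolated_genes, 92)
})
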