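test_that("bivalent mark counting matches direct set membership", {
  db <- list(EZH2 = c("a", "b", "c"), SUZ12 = c("a", "b"),
             H3K27me3 = c("a", "b", "d"), H3K4me2 = c("a", "e"),
             H3K4me3 = c("a", "b"))
  res <- count_bivalent(c("a", "b", "d", "z"), db)
  expect_equal(unname(res$counts), c(5, 4, 1, 0))
  expect_equal(res$summary$n[res$summary$min_marks == 4], 2L)
  expect_equal(res$summary$n[res$summary$min_marks == 5], 1L)
  expect_error(count_bivalent("a", db, marks = c("EZH2", "H3K9me3")),
               "unknown")
  # 100-CpG fixture against a brute-force counting oracle
  set.seed(17)
  ids <- sprintf("cg%03d", 1:100)
  db2 <- lapply(stats::setNames(nm = names(db)),
                function(m) sample(ids, sample(20:60, 1)))
  res2 <- count_bivalent(ids, db2)
  brute <- sapply(ids, function(x)
    sum(vapply(db2, function(s) x %in% s, TRUE)))
  expect_equal(res2$counts, brute)
  expect_equal(res2$summary$fraction, sapply(1:5, function(k) mean(brute >= k)))
})

test_that("heatmap matrix picks the strongest leading-edge CpG per gene", {
  # single gene, one CpG, patient M = 2, control M = 0.5 -> cell 1.5;
  # a second gene with t-stats (-5, 3) must pick the t = -5 CpG
  m <- rbind(cgA = c(0.5, 2, 1, 1), cgB = c(1, 0, 2, 2), cgC = c(0, 1, 0, 1))
  colnames(m) <- c("c1", "p1", "c2", "p2")
  design <- data.frame(sample_id = colnames(m), set = c(1, 1, 2, 2),
                       role = c("control", "patient", "control", "patient"))
  stats <- structure(data.frame(probe_id = c("cgA", "cgB", "cgC"),
                                t = c(4, -5, 3)),
                     class = c("ranked_stats", "data.frame"))
  prom <- structure(data.frame(id = c("G1", "G2")),
                    class = c("gsea_result", "data.frame"))
  prom$leading_edge <- list("cgA", c("cgB", "cgC"))
  cats <- structure(data.frame(id = c("K1", "K2")),
                    class = c("gsea_result", "data.frame"))
  cats$leading_edge <- list(c("G1", "G2"), c("G1", "G2"))
  hm <- heatmap_matrix(cats, c("K1", "K2"), prom, stats, m, design)
  expect_equal(hm$chosen_cpg, c(G2 = "cgB", G1 = "cgA"))
  expect_equal(hm$matrix["G1", "1"], 2 - 0.5)
  # values equal an independent patient-minus-control recomputation
  expect_equal(hm$matrix["G2", "2"], m["cgB", "p2"] - m["cgB", "c2"])
  expect_equal(rownames(hm$matrix)[1], "G2")   # ordered by |t|
  expect_error(heatmap_matrix(cats, "missing", prom, stats, m, design),
               "absent")
})

test_that("heatmap matrix equals a direct recomputation on a simulated cohort", {
  cfg <- small_cohort_config(seed = 61)
  ann <- make_annotation(cfg)
  coh <- simulate_cohort(ann, cfg)
  dm <- run_diffmeth(coh$intensities, coh$design, ann)
  pe <- promoter_enrichment(dm$stats, ann$promoter_map, nperm = 300, seed = 8)
  cg <- chained_gsea(pe, ann$gene_sets, nperm = 300, seed = 9, min_size = 5)
  cats <- cg$id[order(cg$p_adj)][1:3]
  hm <- heatmap_matrix(cg, cats, pe, dm$stats, dm$m, coh$design,
                       top_n = 20, min_membership = 2)
  tvec <- setNames(dm$stats$t, dm$stats$probe_id)
  for (g in hm$genes[1:min(5, length(hm$genes))]) {
    cpg <- hm$chosen_cpg[[g]]
    le <- pe$leading_edge[[match(g, pe$id)]]
    expect_true(cpg %in% le)
    expect_equal(abs(tvec[[cpg]]), max(abs(tvec[le])))
    want <- sapply(1:8, function(i)
      dm$m[cpg, sprintf("p%d", i)] - dm$m[cpg, sprintf("c%d", i)])
    expect_equal(unname(hm$matrix[g, ]), unname(want))
  }
})

test_that("signature correlation handles identity, negation and planted anticorrelation", {
  set.seed(18)
  own <- setNames(rnorm(229, 0, 0.1), sprintf("cg%03d", 1:229))
  expect_equal(signature_correlation(own, own)$r, 1)
  expect_equal(signature_correlation(own, -own)$r, -1)
  expect_equal(signature_correlation(own, own)$n_overlap, 229L)
  expect_error(signature_correlation(own[1:5],
                                     setNames(1:3, c("x", "y", "z"))),
               "overlapping")
  # planted anti-correlated signature: delta = -own + noise (sd 0.5 relative)
  rs <- vapply(1:20, function(s) {
    set.seed(100 + s)
    sig <- data.frame(cpg_id = names(own),
                      delta = -own + rnorm(229, 0, 0.5 * sd(own)))
    signature_correlation(own, sig)$r
  }, 0)
  expect_true(all(rs < -0.4))
})

test_that("linear clocks invert exactly on encoded synthetic betas", {
  # identity transform, single unit coefficient
  beta <- matrix(0.5, 1, 2, dimnames = list("cg1", c("s1", "s2")))
  ck <- clock_model("toy", 0, c(cg1 = 1), "identity")
  expect_equal(unname(apply_clock(beta, ck)), c(0.5, 0.5),
               ignore_attr = TRUE)
  # horvath boundary: linear predictor 0 -> age 20
  ck0 <- clock_model("h", -0.5, c(cg1 = 1), "horvath")
  expect_equal(unname(apply_clock(beta, ck0))[1], 20)
  # encode age 7.3 through the inverse horvath map and recover it
  target_m <- log((7.3 + 1) / 21)          # adult_age 20 transform, m < 0
  coefs <- c(cgA = 0.8, cgB = -1.2, cgC = 2.0)
  b <- c(cgA = 0.3, cgB = 0.6, cgC = 0.25)
  intercept <- target_m - sum(coefs * b)
  ck2 <- clock_model("h2", intercept, coefs, "horvath")
  bm <- matrix(b, 3, 1, dimnames = list(names(b), "s1"))
  expect_equal(unname(apply_clock(bm, ck2)), 7.3, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("clock coverage rules: mean imputation below 5% missing, error beyond", {
  set.seed(19)
  cpgs <- sprintf("cg%03d", 1:100)
  coefs <- setNames(rnorm(100, 0, 0.1), cpgs)
  beta <- matrix(runif(100 * 3), 100, 3, dimnames = list(cpgs, c("a", "b", "c")))
  ck <- clock_model("big", 10, coefs, "identity")
  full <- apply_clock(beta, ck)
  part <- apply_clock(beta[1:96, ], ck)
  expect_equal(attr(part, "n_imputed"), 4L)
  expect_equal(unname(full), unname(part), tolerance = 0.2,
               ignore_attr = TRUE)
  expect_error(apply_clock(beta[1:90, ], ck), "95%")
})

test_that("cell deconvolution recovers mixtures under the simplex constraints", {
  set.seed(20)
  cpgs <- sprintf("cg%03d", 1:200)
  ref <- matrix(runif(200 * 5), 200, 5,
                dimnames = list(cpgs, sprintf("T%d", 1:5)))
  # pure profile: that type gets 1, the rest 0
  pure <- deconvolve_cells(setNames(ref[, 2], cpgs), ref)
  expect_equal(unname(pure$proportions), c(0, 1, 0, 0, 0), tolerance = 1e-8)
  # noiseless 50/50 mixture
  mix <- deconvolve_cells(setNames(0.5 * ref[, 1] + 0.5 * ref[, 3], cpgs), ref)
  expect_equal(unname(mix$proportions), c(0.5, 0, 0.5, 0, 0), tolerance = 1e-6)
  # noisy planted mixtures: L-infinity error < 0.05 at noise sd 0.02
  for (s in 1:20) {
    set.seed(300 + s)
    w <- runif(5); w <- w / sum(w)
    b <- as.numeric(ref %*% w) + rnorm(200, 0, 0.02)
    got <- deconvolve_cells(setNames(b, cpgs), ref)$proportions
    expect_lt(max(abs(got - w)), 0.05)
    expect_true(all(got >= 0))
    expect_lte(sum(got), 1 + 1e-9)
  }
  expect_error(deconvolve_cells(setNames(ref[, 1], cpgs),
                                cbind(ref[, 1], ref[, 1])),
               "rank-deficient")
})

test_that("PCA QC reports coinciding duplicates and unit variance fractions", {
  set.seed(21)
  m <- matrix(rnorm(500 * 3), 500, 3,
              dimnames = list(sprintf("cg%03d", 1:500), c("a", "b", "c")))
  m[, 2] <- m[, 1]                           # two identical samples
  qc <- pca_qc(m, n_top = 500)
  expect_equal(qc$scores[1, ], qc$scores[2, ], tolerance = 1e-10)
  expect_equal(sum(qc$var_explained), 1)
  expect_error(pca_qc(matrix(1, 10, 3,
                             dimnames = list(sprintf("p%d", 1:10),
                                             c("a", "b", "c")))),
               "constant")
})

test_that("PCA recovers planted age-correlated drift on PC1", {
  cfg <- sim_config(n_cpgs = 3000, n_genes = 40, age_drift = 0.1, seed = 62)
  ann <- make_annotation(cfg)
  coh <- simulate_cohort(ann, cfg)
  m <- compute_m(compute_beta(coh$intensities))
  qc <- pca_qc(m, covariates = coh$design[, c("age", "sex")], n_top = 3000)
  expect_gt(abs(cor(qc$scores[, 1], coh$design$age)), 0.8)
  a1 <- qc$associations[qc$associations$pc == 1 &
                          qc$associations$covariate == "age", ]
  expect_lt(a1$p, 0.01)
})
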