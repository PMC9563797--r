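#' Count bivalent chromatin marks per CpG
#'
#' Bivalent promoters carry both activating (H3K4me2/3) and repressive
#' (H3K27me3, polycomb EZH2/SUZ12) marks. For each CpG the number of marks
#' it belongs to is counted and summarised as the fraction carrying at
#' least `k` of the five.
#'
#' @param cpg_ids CpGs to score.
#' @param mark_db named list of CpG-id vectors, one per mark.
#' @param marks mark names to use; all must exist in `mark_db`.
#' @return List with `counts` (named integer vector per CpG) and `summary`
#'   (data.frame `min_marks`, `n`, `fraction` for thresholds 1..length
#'   (marks)).
#' @export
count_bivalent <- function(cpg_ids, mark_db,
                           marks = c("EZH2", "SUZ12", "H3K27me3",
                                     "H3K4me2", "H3K4me3")) {
  missing <- setdiff(marks, names(mark_db))
  if (length(missing))
    stop("unknown marks: ", paste(missing, collapse = ", "))
  counts <- rowSums(vapply(marks, function(m) cpg_ids %in% mark_db[[m]],
                           logical(length(cpg_ids))))
  names(counts) <- cpg_ids
  ks <- seq_along(marks)
  summary <- data.frame(
    min_marks = ks,
    n = vapply(ks, function(k) sum(counts >= k), 0L),
    fraction = vapply(ks, function(k) mean(counts >= k), 0))
  list(counts = counts, summary = summary)
}

#' Patient-vs-control heatmap matrix for top leading-edge genes
#'
#' Builds the gene-by-pair matrix of M-value differences behind the
#' top-CpG heatmap: genes appearing in the leading edge of at least
#' `min_membership` of the given categories are collected; for each such
#' gene the promoter leading-edge CpG with the largest absolute
#' t-statistic is chosen (ties broken by lower probe id); each cell is that
#' CpG's paired delta-M. Rows are ordered by decreasing |t| and truncated
#' to `top_n`.
#'
#' @param category_results `gsea_result` over categories (gene leading
#'   edges).
#' @param categories category ids to combine (e.g. 3 disease categories).
#' @param promoter_results `gsea_result` from [promoter_enrichment()]
#'   (CpG leading edges per gene).
#' @param stats `ranked_stats` (for the per-CpG t).
#' @param m M-value matrix.
#' @param design paired design.
#' @param top_n maximum genes shown (default 100; all if fewer qualify).
#' @param min_membership minimum category membership (default 2).
#' @return List: `matrix` (genes x sets of delta-M), `chosen_cpg` (named
#'   by gene), `genes`.
#' @export
heatmap_matrix <- function(category_results, categories, promoter_results,
                           stats, m, design, top_n = 100L,
                           min_membership = 2L) {
  genes <- leading_edge_genes(category_results, categories, min_membership)
  genes <- intersect(genes, promoter_results$id)
  if (length(genes) == 0L) stop("no qualifying genes")
  tvec <- stats::setNames(stats$t, stats$probe_id)
  chosen <- vapply(genes, function(g) {
    le <- promoter_results$leading_edge[[match(g, promoter_results$id)]]
    le <- le[le %in% names(tvec)]
    if (length(le) == 0L) return(NA_character_)
    le[order(-abs(tvec[le]), le)][1]
  }, "")
  keep <- !is.na(chosen)
  genes <- genes[keep]; chosen <- chosen[keep]
  ord <- order(-abs(tvec[chosen]))
  genes <- genes[ord]; chosen <- chosen[ord]
  if (length(genes) > top_n) { genes <- genes[1:top_n]; chosen <- chosen[1:top_n] }
  dm <- pair_differences(m[chosen, , drop = FALSE], design)
  rownames(dm) <- genes
  list(matrix = dm, chosen_cpg = stats::setNames(chosen, genes), genes = genes)
}

#' Correlate the cohort's methylation deltas with an external signature
#'
#' Pearson correlation, over the intersection of CpG ids, between the
#' cohort's mean patient-minus-control differences and an externally
#' published differential-methylation signature (e.g. another syndrome's
#' significant CpGs).
#'
#' @param own_deltas named numeric vector: per-CpG mean paired difference
#'   (delta-beta or delta-M).
#' @param signature data.frame `cpg_id`, `delta`, or a named numeric
#'   vector.
#' @return List with `r` (Pearson correlation) and `n_overlap`.
#' @export
signature_correlation <- function(own_deltas, signature) {
  if (is.data.frame(signature))
    signature <- stats::setNames(signature$delta, signature$cpg_id)
  shared <- intersect(names(own_deltas), names(signature))
  if (length(shared) < 3L)
    stop("fewer than 3 overlapping CpGs")
  list(r = stats::cor(own_deltas[shared], signature[shared]),
       n_overlap = length(shared))
}

#' Define a linear epigenetic clock
#'
#' @param name clock label.
#' @param intercept model intercept.
#' @param coefficients named numeric vector (CpG id -> coefficient).
#' @param transform `"identity"`, or `"horvath"` (the piecewise log-linear
#'   age transform with adult age 20).
#' @return A list of class `"clock_model"`.
#' @export
clock_model <- function(name, intercept, coefficients,
                        transform = c("identity", "horvath")) {
  transform <- match.arg(transform)
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)),
            all(is.finite(coefficients)), is.finite(intercept))
  structure(list(name = name, intercept = intercept,
                 coefficients = coefficients, transform = transform),
            class = "clock_model")
}

#' Apply a linear epigenetic clock to beta values
#'
#' Computes the linear predictor `m = intercept + sum(coef * beta)` per
#' sample and back-transforms it to years. The Horvath transform inverts
#' the adult-age-20 piecewise map: `age = 21 * exp(m) - 1` for `m < 0`,
#' `age = 21 * m + 20` otherwise. Clock CpGs missing from the matrix are
#' imputed by the cohort mean of the available samples, provided at least
#' 95% of clock CpGs are present.
#'
#' @param beta beta matrix (probes x samples).
#' @param clock a [clock_model()].
#' @return Named numeric vector of per-sample age estimates; the number of
#'   imputed CpGs is attached as attribute `"n_imputed"`.
#' @export
apply_clock <- function(beta, clock) {
  stopifnot(inherits(clock, "clock_model"))
  cpgs <- names(clock$coefficients)
  present <- cpgs %in% rownames(beta)
  if (mean(present) < 0.95)
    stop("fewer than 95% of clock CpGs present (",
         sum(present), "/", length(cpgs), ")")
  b <- matrix(NA_real_, length(cpgs), ncol(beta),
              dimnames = list(cpgs, colnames(beta)))
  b[present, ] <- beta[cpgs[present], , drop = FALSE]
  if (any(!present)) {
    pooled <- mean(b[present, ])
    b[!present, ] <- pooled
  }
  m <- clock$intercept + colSums(b * clock$coefficients)
  age <- switch(clock$transform,
                identity = m,
                horvath = ifelse(m < 0, (1 + 20) * exp(m) - 1,
                                 m * (1 + 20) + 20))
  attr(age, "n_imputed") <- sum(!present)
  age
}

#' Reference-based cell-type deconvolution of a beta profile
#'
#' Constrained least squares: finds nonnegative cell-type weights summing
#' to at most 1 that best reconstruct the sample's betas from the
#' reference profiles, `min ||b - A w||^2 s.t. w >= 0, sum(w) <= 1`. The
#' nonnegative solution is computed by Lawson-Hanson NNLS; if it leaves the
#' simplex, the sum constraint is activated via a heavily weighted
#' normalisation row.
#'
#' @param beta_sample numeric vector (named by CpG) for one sample.
#' @param reference matrix of reference mean betas, CpGs x cell types
#'   (>= 2 types, full column rank).
#' @return List with `proportions` (named, nonnegative, sum <= 1) and
#'   `residual` (norm of the fit residual).
#' @export
deconvolve_cells <- function(beta_sample, reference) {
  stopifnot(is.matrix(reference), ncol(reference) >= 2L)
  if (qr(reference)$rank < ncol(reference))
    stop("reference profile matrix is rank-deficient")
  cpgs <- rownames(reference)
  if (!is.null(cpgs)) {
    if (!all(cpgs %in% names(beta_sample)))
      stop("reference CpGs missing from the sample")
    b <- beta_sample[cpgs]
  } else b <- beta_sample
  w <- pracma::lsqnonneg(reference, as.numeric(b))$x
  if (sum(w) > 1 + 1e-9) {
    lambda <- 1e6 * max(abs(reference))
    aug <- rbind(reference, lambda)
    w <- pracma::lsqnonneg(aug, c(as.numeric(b), lambda))$x
    w <- w / max(1, sum(w))              # clear the penalty's residual slack
  }
  names(w) <- colnames(reference)
  list(proportions = w,
       residual = sqrt(sum((as.numeric(b) - reference %*% w)^2)))
}

#' PCA quality control of an M-value matrix
#'
#' Column-centred SVD of the samples over the top-variance CpGs, with
#' per-component variance fractions and PC-covariate association screens:
#' Pearson correlation (and test) for numeric covariates, Wilcoxon
#' rank-sum for two-level covariates.
#'
#' @param m M-value matrix (probes x samples).
#' @param covariates data.frame of per-sample covariates (row per sample,
#'   in column order of `m`).
#' @param n_top number of highest-variance CpGs used (default 20000,
#'   capped at the matrix size).
#' @param n_pcs number of components screened against covariates.
#' @return List: `scores` (samples x PCs), `var_explained` (fractions
#'   summing to 1), `associations` (data.frame pc, covariate, statistic,
#'   p).
#' @export
pca_qc <- function(m, covariates = NULL, n_top = 20000L, n_pcs = 3L) {
  stopifnot(is.matrix(m), ncol(m) >= 3L)
  v <- apply(m, 1, stats::var)
  if (all(v == 0)) stop("constant matrix")
  top <- order(-v)[seq_len(min(n_top, nrow(m)))]
  x <- t(m[top, , drop = FALSE])
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  assoc <- NULL
  if (!is.null(covariates)) {
    n_pcs <- min(n_pcs, ncol(pc$x))
    rows <- list()
    for (k in seq_len(n_pcs)) for (cv in names(covariates)) {
      val <- covariates[[cv]]
      if (is.numeric(val)) {
        ct <- stats::cor.test(pc$x[, k], val)
        rows[[length(rows) + 1L]] <- data.frame(
          pc = k, covariate = cv, statistic = unname(ct$estimate),
          p = ct$p.value)
      } else if (length(unique(val)) == 2L) {
        wt <- stats::wilcox.test(pc$x[, k] ~ factor(val), exact = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          pc = k, covariate = cv, statistic = unname(wt$statistic),
          p = wt$p.value)
      }
    }
    assoc <- do.call(rbind, rows)
  }
  list(scores = pc$x, var_explained = ve, associations = assoc)
}
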