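#' Select significant CpGs in one direction
#'
#' CpGs with unadjusted `p < alpha` whose effect sign matches the requested
#' direction; `"hypo"` means less methylation in patients (negative t).
#'
#' @param stats a `ranked_stats` data.frame.
#' @param alpha significance cutoff on the unadjusted p (default 0.01).
#' @param direction `"hypo"` or `"hyper"`.
#' @return Character vector of probe ids (possibly empty, with a warning).
#' @export
select_cpgs <- function(stats, alpha = 0.01, direction = c("hypo", "hyper")) {
  direction <- match.arg(direction)
  sgn <- if (direction == "hypo") -1 else 1
  sel <- stats$probe_id[stats$p < alpha & sign(stats$t) == sgn]
  if (length(sel) == 0L)
    warning("no CpGs selected (alpha = ", alpha, ", ", direction, ")")
  sel
}

#' Hypergeometric over-representation of CpG categories
#'
#' For each category, tests whether the selected CpGs overlap it more than
#' expected by chance within the fixed universe: upper-tail hypergeometric
#' `p = P(X >= k)` for `X ~ Hypergeom(N, K, n)` with universe size `N`,
#' category size `K` (after intersection with the universe), selection size
#' `n` and overlap `k`. Categories whose in-universe size is below `min_gs`
#' are skipped. The odds ratio is `(k/(n-k)) / ((K-k)/(N-K-n+k))` with a
#' Haldane 0.5 correction when any cell is zero.
#'
#' @param selected character vector of selected CpG ids; must be a subset
#'   of `universe`.
#' @param category_db named list of CpG-id vectors.
#' @param universe character vector: the analysis universe (all tested
#'   CpGs).
#' @param min_gs minimum in-universe category size (default 4).
#' @param max_gs maximum category size (default `Inf`).
#' @param direction optional label (`"hypo"`/`"hyper"`) copied to the
#'   output.
#' @return Data.frame: `category`, `universe_size`, `category_size`,
#'   `selected_size`, `overlap`, `odds_ratio`, `p`, `p_adj`, `direction`.
#' @export
cpg_ora <- function(selected, category_db, universe, min_gs = 4L,
                    max_gs = Inf, direction = NA_character_) {
  if (!all(selected %in% universe))
    stop("selected CpGs must be a subset of the universe")
  universe <- unique(universe)
  selected <- unique(selected)
  N <- length(universe)
  n <- length(selected)
  cats <- lapply(category_db, intersect, universe)
  K <- vapply(cats, length, 0L)
  keep <- K >= min_gs & K <= max_gs
  cats <- cats[keep]; K <- K[keep]
  if (length(cats) == 0L) stop("no category passes the size filter")
  k <- vapply(cats, function(cc) length(intersect(cc, selected)), 0L)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  oddsr <- mapply(function(k, K) {
    a <- k; b <- n - k; c <- K - k; d <- N - K - n + k
    if (any(c(a, b, c, d) == 0)) { a <- a + .5; b <- b + .5; c <- c + .5; d <- d + .5 }
    (a / b) / (c / d)
  }, k, K)
  data.frame(category = names(cats), universe_size = N, category_size = K,
             selected_size = n, overlap = k, odds_ratio = oddsr,
             p = p, p_adj = adjust_bh(p), direction = direction,
             row.names = NULL)
}

#' Direction-split ORA with optional region-exclusion rerun
#'
#' Recomputes the moderated-t stage on the universe with the masked probes
#' removed, reselects significant CpGs in both directions, and runs
#' [cpg_ora()] with universe, selection and statistics all restricted to the
#' reduced probe set. With an empty mask this is the plain direction-split
#' analysis of the full universe.
#'
#' @param intensities an [intensity_matrix()].
#' @param design paired design data.frame.
#' @param annotation probe annotation (filter flags + positions).
#' @param category_db named list of CpG-id sets.
#' @param exclude_probes probe ids to mask (e.g.
#'   `region_probes(ann, "chr5", 0, ann$p_arm_end)`); `NULL` for none.
#' @param alpha,min_gs,max_gs see [select_cpgs()] and [cpg_ora()].
#' @param covariates optional set-level covariates for the t-stage.
#' @return List with `hypo` and `hyper` ORA tables, `stats`, and `universe`.
#' @export
exclusion_rerun <- function(intensities, design, annotation, category_db,
                            exclude_probes = NULL, alpha = 0.01,
                            min_gs = 4L, max_gs = Inf, covariates = NULL) {
  all_ids <- rownames(intensities$meth)
  keep <- if (is.null(exclude_probes)) NULL else setdiff(all_ids, exclude_probes)
  dm <- run_diffmeth(intensities, design, annotation,
                     covariates = covariates, probes = keep)
  universe <- dm$retained
  res <- lapply(c(hypo = "hypo", hyper = "hyper"), function(dir) {
    sel <- suppressWarnings(select_cpgs(dm$stats, alpha, dir))
    if (length(sel) == 0L) return(NULL)
    cpg_ora(sel, category_db, universe, min_gs, max_gs, direction = dir)
  })
  list(hypo = res$hypo, hyper = res$hyper, stats = dm$stats,
       universe = universe)
}
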