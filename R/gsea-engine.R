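#' Rank items by a statistic
#'
#' Descending order with deterministic tie-breaking by item id. An optional
#' exclusion set is removed before ranking (for genomic exclusions the
#' t-statistic stage should itself be rerun on the reduced universe; see
#' [run_diffmeth()]'s `probes` argument).
#'
#' @param x a `ranked_stats` data.frame (ranked by `t`) or a named numeric
#'   vector of statistics.
#' @param exclude optional character vector of ids to drop before ranking.
#' @return A list of class `"ranked_list"`: `ids`, `stats` (same order).
#' @export
rank_items <- function(x, exclude = NULL) {
  if (inherits(x, "ranked_stats")) {
    stats <- stats::setNames(x$t, x$probe_id)
  } else {
    stopifnot(is.numeric(x), !is.null(names(x)))
    stats <- x
  }
  if (!all(is.finite(stats))) stop("ranking statistics must be finite")
  if (!is.null(exclude)) stats <- stats[!names(stats) %in% exclude]
  if (length(stats) < 10L) stop("fewer than 10 items after exclusion")
  ord <- order(-stats, names(stats), method = "radix")
  structure(list(ids = names(stats)[ord], stats = unname(stats[ord])),
            class = "ranked_list")
}

## Enrichment score from sorted hit positions.
## Hits add |r|^p / sum_hits(|r|^p); misses subtract 1/(N - m). The running
## sum is piecewise: its maximum sits at a hit, its minimum just before one,
## so only 2m candidate values need inspecting. Zero total hit weight (all
## statistics zero) falls back to equal hit weights.
es_from_hits <- function(hits, weights, n) {
  m <- length(hits)
  w <- weights
  if (sum(w) == 0) w <- rep(1, m)
  cumw <- cumsum(w) / sum(w)
  d <- if (n > m) 1 / (n - m) else 0
  miss_before <- (hits - seq_len(m)) * d
  at_hit <- cumw - miss_before                 # value at each hit
  before_hit <- c(0, cumw[-m]) - miss_before   # value just before each hit
  max_a <- max(at_hit); j_a <- which.max(at_hit)
  min_b <- min(before_hit); j_b <- which.min(before_hit)
  if (max_a + min_b >= -1e-12)   # positive preference on (numerical) ties
    list(es = max_a, extremum = hits[j_a], leading_idx = seq_len(j_a))
  else
    list(es = min_b, extremum = hits[j_b] - 1L, leading_idx = j_b:m)
}

#' Weighted-KS enrichment score of a member set in a ranked list
#'
#' Classic running-sum statistic: walking down the ranking, members add
#' `|r_i|^p / sum_members(|r_j|^p)` and non-members subtract `1/(N - m)`;
#' the enrichment score is the extremum of largest absolute deviation (ties
#' resolved towards the positive extremum). The leading edge contains the
#' members at or before a positive extremum, and at or after a negative one.
#'
#' @param ranked a [rank_items()] result.
#' @param members character vector of member ids; must intersect the
#'   ranking.
#' @param weight_p weighting exponent on the ranking statistic (default 1).
#' @return List with `es` (in \[-1, 1\]), `extremum` (rank position) and
#'   `leading_edge` (member ids).
#' @export
es_score <- function(ranked, members, weight_p = 1) {
  stopifnot(inherits(ranked, "ranked_list"))
  hits <- sort(match(members, ranked$ids))
  hits <- hits[!is.na(hits)]
  if (length(hits) == 0L) stop("member set is disjoint from the ranked list")
  r <- es_from_hits(hits, abs(ranked$stats[hits])^weight_p, length(ranked$ids))
  list(es = r$es, extremum = r$extremum,
       leading_edge = ranked$ids[hits[r$leading_idx]])
}

#' Preranked GSEA with a random-set permutation null
#'
#' Each set's enrichment score is compared against the scores of `nperm`
#' random same-size subsets of the ranked items (sampling without
#' replacement, seeded; nulls are shared between sets of equal size). The
#' normalized score divides by the mean absolute null score of matching
#' sign, and the p-value is sign-conditional with a pseudocount so it is
#' never 0:
#' `p = (#{same-sign nulls with |ES_null| >= |ES|} + 1) / (#same-sign + 1)`.
#' Benjamini-Hochberg adjustment is applied across tested sets.
#'
#' A ranking whose statistics are all identical carries no order
#' information; every set is then reported with `NES = 0`, `p = 1`.
#'
#' @param ranked a [rank_items()] result.
#' @param sets named list of member-id vectors.
#' @param nperm number of permutations (>= 100), default 1000.
#' @param seed integer seed for the null sampling.
#' @param min_size,max_size set-size filter applied after intersection with
#'   the ranked universe; out-of-range sets are skipped and recorded.
#' @param weight_p weighting exponent, default 1.
#' @return A data.frame of class `"gsea_result"`: `id`, `size`, `es`, `nes`,
#'   `p`, `p_adj`, `leading_edge` (list column); skipped set ids in
#'   attribute `"skipped"`.
#' @export
preranked_gsea <- function(ranked, sets, nperm = 1000L, seed = 1L,
                           min_size = 10L, max_size = 500L, weight_p = 1) {
  stopifnot(inherits(ranked, "ranked_list"), nperm >= 100L)
  n <- length(ranked$ids)
  hit_list <- lapply(sets, function(s) sort(match(s, ranked$ids)))
  hit_list <- lapply(hit_list, function(h) h[!is.na(h)])
  sizes <- vapply(hit_list, length, 0L)
  keep <- sizes >= min_size & sizes <= max_size
  if (!any(keep)) stop("no set passes the size filter")
  skipped <- names(sets)[!keep]
  hit_list <- hit_list[keep]
  sizes <- sizes[keep]
  ids <- names(sets)[keep]
  ord <- order(ids)                      # deterministic processing order
  hit_list <- hit_list[ord]; sizes <- sizes[ord]; ids <- ids[ord]

  w_full <- abs(ranked$stats)^weight_p
  degenerate <- diff(range(ranked$stats)) == 0

  obs <- lapply(hit_list, function(h) es_from_hits(h, w_full[h], n))
  es <- vapply(obs, `[[`, 0, "es")

  if (degenerate) {
    nes <- rep(0, length(es)); p <- rep(1, length(es))
  } else {
    set.seed(seed)
    null_by_size <- list()
    for (s in sort(unique(sizes))) {
      null_by_size[[as.character(s)]] <- vapply(seq_len(nperm), function(b) {
        h <- sort(sample.int(n, s))
        es_from_hits(h, w_full[h], n)$es
      }, 0)
    }
    nes <- p <- numeric(length(es))
    for (i in seq_along(es)) {
      null <- null_by_size[[as.character(sizes[i])]]
      sgn <- if (es[i] >= 0) 1 else -1
      same <- null[sign(null) == sgn | null == 0]
      if (length(same) == 0L) same <- null
      nes[i] <- if (mean(abs(same)) > 0) es[i] / mean(abs(same)) else 0
      p[i] <- (sum(abs(same) >= abs(es[i])) + 1) / (length(same) + 1)
    }
  }
  out <- data.frame(id = ids, size = sizes, es = es, nes = nes, p = p,
                    p_adj = adjust_bh(p), row.names = NULL)
  out$leading_edge <- lapply(seq_along(ids), function(i)
    ranked$ids[hit_list[[i]][obs[[i]]$leading_idx]])
  attr(out, "skipped") <- skipped
  attr(out, "nperm") <- nperm
  class(out) <- c("gsea_result", "data.frame")
  out
}

#' Per-gene promoter (or gene-body) enrichment from ranked CpGs
#'
#' Integrates CpG-level moderated t-statistics into one result per gene:
#' each gene's promoter (or gene-body) CpG set is tested by
#' [preranked_gsea()] against the full CpG ranking, and summarised by the
#' signed significance score `sign(NES) * -log10(p.adj)` (adjusted p floored
#' at 1e-16 so scores stay finite).
#'
#' @param stats a `ranked_stats` data.frame (or named statistic vector).
#' @param map data.frame `probe_id`, `gene` linking CpGs to gene regions.
#' @param nperm,seed,weight_p passed to [preranked_gsea()].
#' @param min_cpgs minimum mapped CpGs per tested gene (default 5); genes
#'   below it are skipped and recorded.
#' @param exclude optional CpG ids to drop from the ranking (note: for
#'   genomic exclusions rerun the t-stage on the reduced universe first).
#' @return A `gsea_result` with an additional `score` column.
#' @export
promoter_enrichment <- function(stats, map, nperm = 1000L, seed = 1L,
                                min_cpgs = 5L, weight_p = 1, exclude = NULL) {
  stopifnot(all(c("probe_id", "gene") %in% names(map)))
  ranked <- rank_items(stats, exclude = exclude)
  sets <- split(map$probe_id, map$gene)
  res <- preranked_gsea(ranked, sets, nperm = nperm, seed = seed,
                        min_size = min_cpgs, max_size = Inf,
                        weight_p = weight_p)
  res$score <- gene_score(res$nes, res$p_adj)
  res
}

#' Signed significance score for a gene or category
#'
#' `sign(NES) * -log10(p.adj)`, with `p.adj` floored at 1e-16.
#'
#' @param nes normalized enrichment scores.
#' @param p_adj adjusted p-values.
#' @return Numeric scores.
#' @export
gene_score <- function(nes, p_adj) {
  sign(nes) * -log10(pmax(p_adj, 1e-16))
}

#' Category-level GSEA chained on gene promoter scores
#'
#' Genes are ranked by their signed promoter score and functional categories
#' (GO/disease-gene-network style gene sets) are tested by
#' [preranked_gsea()]. A negative category NES means less CpG methylation in
#' patients for that category's gene promoters.
#'
#' @param gene_scores named numeric vector of per-gene scores, or a
#'   `gsea_result` from [promoter_enrichment()] (its `score` column is
#'   used).
#' @param gene_set_db named list of gene-id vectors (e.g. from
#'   [read_gmt()]).
#' @param nperm,seed,min_size,max_size,weight_p passed to
#'   [preranked_gsea()].
#' @return A `gsea_result` over categories, with `score` column.
#' @export
chained_gsea <- function(gene_scores, gene_set_db, nperm = 1000L, seed = 1L,
                         min_size = 10L, max_size = 500L, weight_p = 1) {
  if (inherits(gene_scores, "gsea_result"))
    gene_scores <- stats::setNames(gene_scores$score, gene_scores$id)
  ranked <- rank_items(gene_scores)
  res <- preranked_gsea(ranked, gene_set_db, nperm = nperm, seed = seed,
                        min_size = min_size, max_size = max_size,
                        weight_p = weight_p)
  res$score <- gene_score(res$nes, res$p_adj)
  res
}

#' Genes recurring in the leading edges of several categories
#'
#' @param results a `gsea_result` over categories.
#' @param categories category ids to intersect (must be present in
#'   `results`).
#' @param min_membership minimum number of leading edges a gene must appear
#'   in (default 2).
#' @return Sorted character vector of gene ids.
#' @export
leading_edge_genes <- function(results, categories, min_membership = 2L) {
  stopifnot(inherits(results, "gsea_result"))
  if (!all(categories %in% results$id))
    stop("categories absent from results: ",
         paste(setdiff(categories, results$id), collapse = ", "))
  edges <- results$leading_edge[match(categories, results$id)]
  counts <- table(unlist(edges))
  sort(names(counts)[counts >= min_membership])
}

#' Probe ids inside a genomic region
#'
#' Convenience mask builder for region-exclusion reruns (half-open
#' `[start, end)` on 1-based positions).
#'
#' @param annotation `cpg_annotation` or probe data.frame.
#' @param chromosome chromosome name.
#' @param start,end region bounds (defaults: whole chromosome).
#' @return Character vector of probe ids in the region.
#' @export
region_probes <- function(annotation, chromosome, start = 0, end = Inf) {
  ann <- if (inherits(annotation, "cpg_annotation")) annotation$probes else annotation
  ann$probe_id[ann$chrom == chromosome & ann$pos >= start & ann$pos < end]
}
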