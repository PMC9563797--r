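test_that("ranking is descending with deterministic id tie-breaks and mask semantics", {
  x <- c(b = 2, a = 2, c = 5, d = -1, e = 0, f = 1, g = 3, h = 2.5, i = 0.2,
         j = -3, k = 7, l = 4)
  r <- rank_items(x)
  expect_equal(r$ids[1], "k")
  expect_equal(r$stats, sort(unname(x), decreasing = TRUE))
  # equal statistics ordered by id, stably across runs
  tie_pos <- which(r$stats == 2)
  expect_equal(r$ids[tie_pos], c("a", "b"))
  expect_identical(rank_items(x), rank_items(x))
  r2 <- rank_items(x, exclude = c("c", "k"))
  expect_false(any(c("c", "k") %in% r2$ids))
  expect_error(rank_items(x, exclude = names(x)[1:9]), "fewer than 10")
  expect_error(rank_items(c(a = 1, b = NaN, c = 1, d = 1, e = 1, f = 1,
                            g = 1, h = 1, i = 1, j = 1)), "finite")
})

test_that("enrichment score matches hand enumeration and the exhaustive oracle", {
  # N=3, set = {top item}, stats (3,2,1), p=1: running sum hits 1 at rank 1
  r3 <- rank_items(c(x = 3, y = 2, z = 1, a = -1, b = -2, c = -3, d = 0.5,
                     e = 0.1, f = -0.1, g = 0.2))
  es <- es_score(r3, "x")
  expect_equal(es$es, 1)
  expect_equal(es$extremum, 1L)
  expect_equal(es$leading_edge, "x")
  # set = all items: no misses, ES = 1 at the end
  expect_equal(es_score(r3, r3$ids)$es, 1)

  # all 2^8 - 1 non-empty subsets of an 8-item list, two stat profiles
  for (stats8 in list(c(5, 4, 3, 2, 1.5, 1, 0.5, 0.1),
                      c(3, 2, 1, 0.5, -0.2, -1, -2, -4))) {
    names(stats8) <- letters[1:8]
    # rank_items requires >= 10 items; build the ranked list directly
    ranked <- structure(list(ids = letters[1:8], stats = unname(stats8)),
                        class = "ranked_list")
    for (mask in 1:255) {
      members <- letters[1:8][bitwAnd(mask, 2^(0:7)) > 0]
      got <- es_score(ranked, members)$es
      want <- es_oracle(ranked$stats, match(members, ranked$ids))
      expect_equal(got, want, tolerance = 1e-9)
    }
  }
})

test_that("enrichment score agrees with an external weighted-KS implementation", {
  set.seed(8)
  stats <- sort(rnorm(200), decreasing = TRUE)
  names(stats) <- sprintf("g%03d", 1:200)
  ranked <- rank_items(stats)
  for (i in 1:20) {
    pos <- sort(sample.int(200, 15))
    expect_equal(es_score(ranked, ranked$ids[pos])$es,
                 fgsea::calcGseaStat(ranked$stats, pos, gseaParam = 1),
                 tolerance = 1e-10)
  }
})

test_that("preranked GSEA is deterministic and flags planted signal", {
  set.seed(9)
  stats <- rnorm(10000)
  names(stats) <- sprintf("g%05d", 1:10000)
  ranked <- rank_items(stats)
  sets <- list(planted = ranked$ids[1:20],
               random1 = sample(names(stats), 30),
               random2 = sample(names(stats), 30))
  res <- preranked_gsea(ranked, sets, nperm = 2000, seed = 4, min_size = 10)
  res2 <- preranked_gsea(ranked, sets, nperm = 2000, seed = 4, min_size = 10)
  expect_identical(res$p, res2$p)
  pl <- res[res$id == "planted", ]
  expect_lt(pl$p_adj, 0.01)
  expect_gt(pl$nes, 0)
  expect_true(all(res$p > 0))
  expect_true(all(abs(res$es) <= 1))
  expect_equal(sign(res$nes), sign(res$es))
  # leading edge is a subset of the set, concentrated at the top for planted
  expect_true(all(pl$leading_edge[[1]] %in% sets$planted))
})

test_that("random-set p-values are uniform under the null", {
  set.seed(10)
  stats <- rnorm(1000)
  names(stats) <- sprintf("g%04d", 1:1000)
  ranked <- rank_items(stats)
  ps <- vapply(1:200, function(i) {
    members <- sample(names(stats), 30)
    preranked_gsea(ranked, list(s = members), nperm = 199, seed = 1000 + i,
                   min_size = 10)$p
  }, 0)
  expect_lt(abs(mean(ps < 0.1) - 0.1), 0.05)
})

test_that("negating the ranking statistics negates ES and NES", {
  set.seed(11)
  stats <- rnorm(500)
  names(stats) <- sprintf("g%03d", 1:500)
  members <- sample(names(stats), 40)
  res <- preranked_gsea(rank_items(stats), list(s = members), nperm = 500,
                        seed = 2, min_size = 10)
  neg <- preranked_gsea(rank_items(-stats), list(s = members), nperm = 500,
                        seed = 2, min_size = 10)
  expect_equal(neg$es, -res$es, tolerance = 1e-12)
  expect_equal(sign(neg$nes), -sign(res$nes))
  # p preserved within Monte-Carlo error (binomial SE at nperm = 500)
  se <- sqrt(res$p * (1 - res$p) / 250)
  expect_lt(abs(neg$p - res$p), 4 * se + 0.02)
})

test_that("doubling nperm moves p by less than 3 Monte-Carlo standard errors", {
  set.seed(12)
  stats <- rnorm(800)
  names(stats) <- sprintf("g%03d", 1:800)
  members <- c(names(sort(stats, decreasing = TRUE))[1:10],
               sample(names(stats), 20))
  p1 <- preranked_gsea(rank_items(stats), list(s = members), nperm = 500,
                       seed = 3, min_size = 10)$p
  p2 <- preranked_gsea(rank_items(stats), list(s = members), nperm = 1000,
                       seed = 4, min_size = 10)$p
  se <- sqrt(p1 * (1 - p1) / 250)
  expect_lt(abs(p1 - p2), 3 * se + 0.01)
})

test_that("size filtering skips and records out-of-range sets", {
  set.seed(13)
  stats <- rnorm(100)
  names(stats) <- sprintf("g%03d", 1:100)
  sets <- list(small = names(stats)[1:3], ok = names(stats)[1:20],
               big = names(stats))
  res <- preranked_gsea(rank_items(stats), sets, nperm = 100, min_size = 10,
                        max_size = 50)
  expect_equal(res$id, "ok")
  expect_setequal(attr(res, "skipped"), c("small", "big"))
  expect_error(preranked_gsea(rank_items(stats), list(s = names(stats)[1:2]),
                              nperm = 100, min_size = 10), "size filter")
})

test_that("promoter enrichment scores planted genes and keeps nulls quiet", {
  cfg <- small_cohort_config(seed = 41)
  ann <- make_annotation(cfg)
  coh <- simulate_cohort(ann, cfg)
  dm <- run_diffmeth(coh$intensities, coh$design, ann)
  pe <- promoter_enrichment(dm$stats, ann$promoter_map, nperm = 500, seed = 5)
  planted_genes <- intersect(ann$gene_sets[["GS01"]], pe$id)
  null_genes <- setdiff(pe$id, planted_genes)
  expect_true(all(pe[match(planted_genes, pe$id), "score"] < 0))
  expect_true(all(pe[match(planted_genes, pe$id), "p_adj"] < 0.05))
  expect_gt(median(pe[match(null_genes, pe$id), "p"]), 0.2)
  # score arithmetic: sign(NES) * -log10(p.adj)
  expect_equal(pe$score, sign(pe$nes) * -log10(pmax(pe$p_adj, 1e-16)))
  expect_equal(gene_score(-2, 0.01), -2)
})

test_that("chained category GSEA ranks the planted set first with negative NES", {
  cfg <- small_cohort_config(seed = 42)
  ann <- make_annotation(cfg)
  coh <- simulate_cohort(ann, cfg)
  dm <- run_diffmeth(coh$intensities, coh$design, ann)
  pe <- promoter_enrichment(dm$stats, ann$promoter_map, nperm = 500, seed = 6)
  cg <- chained_gsea(pe, ann$gene_sets, nperm = 1000, seed = 7, min_size = 5)
  expect_equal(cg$id[which.min(cg$p_adj)], "GS01")
  expect_lt(cg$nes[cg$id == "GS01"], 0)  # hypomethylated: negative NES
})

test_that("leading-edge membership filtering matches direct set counting", {
  res <- structure(data.frame(id = c("A", "B", "C")), class = c("gsea_result", "data.frame"))
  res$leading_edge <- list(c("g1", "g2", "g3"), c("g2", "g3", "g4"), c("g3", "g5"))
  expect_equal(leading_edge_genes(res, c("A", "B", "C"), 2), c("g2", "g3"))
  expect_equal(leading_edge_genes(res, c("A", "B"), 2), c("g2", "g3"))
  # identical leading edges pass through unchanged
  res$leading_edge <- list(c("g1", "g2"), c("g1", "g2"), c("g9"))
  expect_equal(leading_edge_genes(res, c("A", "B"), 2), c("g1", "g2"))
  # disjoint edges with min 2 give the empty set
  res$leading_edge <- list("g1", "g2", "g3")
  expect_length(leading_edge_genes(res, c("A", "B", "C"), 2), 0)
  # counting oracle on a random 3-category fixture
  set.seed(14)
  res$leading_edge <- lapply(1:3, function(i) sample(sprintf("g%02d", 1:20), 8))
  want <- names(which(table(unlist(res$leading_edge)) >= 2))
  expect_setequal(leading_edge_genes(res, c("A", "B", "C"), 2), want)
  expect_error(leading_edge_genes(res, "Z"), "absent")
})

test_that("region masks select exactly the probes inside the half-open window", {
  ann <- data.frame(probe_id = sprintf("cg%d", 1:6),
                    chrom = c("chr5", "chr5", "chr5", "chr2", "chr5", "chr5"),
                    pos = c(1, 100, 200, 150, 300, 400))
  expect_equal(region_probes(ann, "chr5", 100, 300), c("cg2", "cg3"))
  expect_equal(region_probes(ann, "chr5"), sprintf("cg%d", c(1, 2, 3, 5, 6)))
})
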