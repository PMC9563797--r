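#' Build a synthetic CpG annotation with gene, category and gene-set databases
#'
#' Lays out non-overlapping genes on the configured chromosomes, scatters
#' CpGs so that every promoter carries at least
#' `config$min_cpgs_per_promoter` probes, and assembles the companion
#' databases the downstream analysis consumes: island relation, toy chromHMM
#' states, five bivalent chromatin marks (EZH2, SUZ12, H3K27me3, H3K4me2,
#' H3K4me3) and a gene-set (category) database.
#'
#' Coordinates are 1-based; all intervals are half-open `[start, end)`.
#' Promoters span `TSS-2000 .. TSS+500`, gene bodies follow the promoter.
#' Output is fully deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return A list of class `"cpg_annotation"` with elements `probes`
#'   (data.frame: probe_id, chrom, pos, island, chromhmm, snp_flag, sex_flag,
#'   promoter_gene, body_gene), `genes`, `promoter_map`, `body_map`,
#'   `gene_sets` (named list of gene vectors), `mark_db` (named list of CpG
#'   id vectors), `category_db` (island + chromHMM + marks as CpG sets),
#'   `bivalent_genes`, and `p_arm_end`.
#' @export
make_annotation <- function(config) {
  validate_sim_config(config)
  cfg <- config
  set.seed(cfg$seed)

  chroms <- names(cfg$chrom_lengths)
  lens <- as.numeric(cfg$chrom_lengths)

  ## -- gene layout: slot the chromosome so windows cannot collide
  footprint <- 2000 + 500 + cfg$gene_body_len + 5000  # promoter + body + gap
  genes_per_chrom <- pmax(1L, round(cfg$n_genes * lens / sum(lens)))
  ## keep total exactly n_genes
  while (sum(genes_per_chrom) > cfg$n_genes)
    genes_per_chrom[which.max(genes_per_chrom)] <-
      genes_per_chrom[which.max(genes_per_chrom)] - 1L
  while (sum(genes_per_chrom) < cfg$n_genes)
    genes_per_chrom[which.max(lens / genes_per_chrom)] <-
      genes_per_chrom[which.max(lens / genes_per_chrom)] + 1L

  gene_rows <- vector("list", length(chroms))
  for (i in seq_along(chroms)) {
    ng <- genes_per_chrom[i]
    n_slots <- floor(lens[i] / footprint)
    if (ng > n_slots)
      stop("impossible packing: ", ng, " genes do not fit on ", chroms[i])
    slots <- sort(sample.int(n_slots, ng))
    slot_start <- (slots - 1) * footprint + 1
    tss <- slot_start + 2000 + floor(stats::runif(ng, 0, 2000))
    gene_rows[[i]] <- data.frame(
      chrom = chroms[i], tss = tss,
      promoter_start = tss - 2000, promoter_end = tss + 500,
      body_start = tss + 500, body_end = tss + 500 + cfg$gene_body_len,
      stringsAsFactors = FALSE
    )
  }
  genes <- do.call(rbind, gene_rows)
  genes <- genes[order(match(genes$chrom, chroms), genes$tss), ]
  genes$gene <- sprintf("G%04d", seq_len(nrow(genes)))
  genes <- genes[, c("gene", "chrom", "tss", "promoter_start",
                     "promoter_end", "body_start", "body_end")]

  ## -- CpG positions: guaranteed promoter CpGs + uniform background
  n_prom_cpgs <- nrow(genes) * cfg$min_cpgs_per_promoter
  if (n_prom_cpgs > cfg$n_cpgs)
    stop("n_cpgs too small for min_cpgs_per_promoter * n_genes")
  prom_pos <- data.frame(
    chrom = rep(genes$chrom, each = cfg$min_cpgs_per_promoter),
    pos = rep(genes$promoter_start, each = cfg$min_cpgs_per_promoter) +
      floor(stats::runif(n_prom_cpgs, 0, 2500))
  )
  n_bg <- cfg$n_cpgs - n_prom_cpgs
  bg_chrom <- sample(chroms, n_bg, replace = TRUE, prob = lens / sum(lens))
  bg_pos <- floor(stats::runif(n_bg, 0,
                               cfg$chrom_lengths[bg_chrom])) + 1
  probes <- rbind(prom_pos, data.frame(chrom = bg_chrom, pos = bg_pos))
  ## enforce unique positions per chromosome (redraw duplicates)
  for (attempt in 1:20) {
    dup <- duplicated(probes[c("chrom", "pos")])
    if (!any(dup)) break
    probes$pos[dup] <- floor(stats::runif(
      sum(dup), 0, cfg$chrom_lengths[probes$chrom[dup]])) + 1
  }
  probes <- probes[order(match(probes$chrom, chroms), probes$pos), ]
  rownames(probes) <- NULL
  probes$probe_id <- sprintf("cg%06d", seq_len(nrow(probes)))

  ## -- map CpGs to promoters / bodies (genes are non-overlapping)
  probes$promoter_gene <- map_interval(probes, genes, "promoter_start", "promoter_end")
  probes$body_gene <- map_interval(probes, genes, "body_start", "body_end")

  in_prom <- !is.na(probes$promoter_gene)
  probes$island <- ifelse(
    in_prom,
    sample(c("Island", "Shore", "OpenSea"), nrow(probes), TRUE, c(.7, .2, .1)),
    sample(c("Island", "Shore", "OpenSea"), nrow(probes), TRUE, c(.1, .2, .7)))
  probes$chromhmm <- ifelse(
    in_prom,
    sample(c("TssA", "TssBiv", "Enh", "Tx", "Het", "Quies"), nrow(probes),
           TRUE, c(.45, .2, .15, .1, .05, .05)),
    sample(c("TssA", "TssBiv", "Enh", "Tx", "Het", "Quies"), nrow(probes),
           TRUE, c(.03, .02, .15, .2, .25, .35)))
  probes$snp_flag <- stats::runif(nrow(probes)) < 0.01
  probes$sex_flag <- probes$chrom %in% c("chrX", "chrY")

  ## -- gene sets; planted sets optionally kept off chr5
  set_ids <- sprintf("GS%02d", seq_len(cfg$n_gene_sets))
  planted_ids <- if (is.null(cfg$planted_sets)) character(0) else
    cfg$planted_sets$set
  if (!all(planted_ids %in% set_ids))
    stop("planted set ids must be among the generated set ids: ",
         paste(set_ids, collapse = ", "))
  off5 <- genes$gene[genes$chrom != "chr5"]
  gene_sets <- list()
  used_planted <- character(0)
  for (sid in set_ids) {
    ## planted sets may overlap one another (disease categories share genes)
    pool <- if (sid %in% planted_ids && cfg$planted_off_chr5)
      off5 else genes$gene
    sz <- min(cfg$gene_set_size, length(pool))
    gene_sets[[sid]] <- sort(sample(pool, sz))
    if (sid %in% planted_ids)
      used_planted <- union(used_planted, gene_sets[[sid]])
  }

  ## -- bivalent marks anchored on planted-set genes plus random extras
  n_biv_target <- max(length(used_planted), ceiling(0.2 * nrow(genes)))
  extra <- sample(setdiff(genes$gene, used_planted),
                  max(0L, n_biv_target - length(used_planted)))
  bivalent_genes <- sort(c(used_planted, extra))
  anchor <- probes$probe_id[!is.na(probes$promoter_gene) &
                              probes$promoter_gene %in% bivalent_genes]
  marks <- c("EZH2", "SUZ12", "H3K27me3", "H3K4me2", "H3K4me3")
  mark_db <- list(EZH2 = anchor)
  other <- setdiff(probes$probe_id, anchor)
  for (m in marks[-1]) {
    on_anchor <- anchor[stats::runif(length(anchor)) < cfg$bivalent_cooccurrence]
    on_bg <- other[stats::runif(length(other)) < cfg$bivalent_background]
    mark_db[[m]] <- sort(c(on_anchor, on_bg))
  }

  category_db <- c(
    split(probes$probe_id, probes$island),
    split(probes$probe_id, paste0("chromHMM_", probes$chromhmm)),
    mark_db
  )

  ann <- list(probes = probes[, c("probe_id", "chrom", "pos", "island",
                                  "chromhmm", "snp_flag", "sex_flag",
                                  "promoter_gene", "body_gene")],
              genes = genes,
              promoter_map = stats::na.omit(data.frame(
                probe_id = probes$probe_id, gene = probes$promoter_gene)),
              body_map = stats::na.omit(data.frame(
                probe_id = probes$probe_id, gene = probes$body_gene)),
              gene_sets = gene_sets, mark_db = mark_db,
              category_db = category_db, bivalent_genes = bivalent_genes,
              p_arm_end = cfg$p_arm_end, config = cfg)
  class(ann) <- "cpg_annotation"
  ann
}

## assign each probe the gene whose [start,end) window contains it; NA if none
map_interval <- function(probes, genes, start_col, end_col) {
  out <- rep(NA_character_, nrow(probes))
  for (ch in unique(probes$chrom)) {
    g <- genes[genes$chrom == ch, ]
    if (nrow(g) == 0) next
    idx <- which(probes$chrom == ch)
    hit <- findInterval(probes$pos[idx], g[[start_col]])
    ok <- hit > 0 & probes$pos[idx] < g[[end_col]][pmax(hit, 1L)]
    out[idx[ok]] <- g$gene[hit[ok]]
  }
  out
}

#' Simulate a paired patient/control cohort on a synthetic annotation
#'
#' Draws a bimodal baseline beta per CpG, lognormal total intensities, and
#' produces methylated/unmethylated signals `meth = T * beta`,
#' `unmeth = T * (1 - beta)` per probe and sample. Patient samples have the
#' total intensity halved for chr5 CpGs below their deletion breakpoint
#' (hemizygosity: one lost allele halves copy number), and promoter CpGs of
#' planted gene sets shifted by the configured delta-beta. A configured
#' fraction of probes fails detection (p >= 0.01) in one random sample.
#'
#' @param annotation a [make_annotation()] result.
#' @param config the same [sim_config()] used for the annotation.
#' @return A list of class `"sim_cohort"`: `intensities` (an
#'   [intensity_matrix()]), `design` (data.frame sample_id, set, role, age,
#'   sex), `truth` (breakpoints, per-CpG delta-beta, planted memberships,
#'   bivalent marks), and `betas` (the noiseless per-sample betas actually
#'   used, for oracle checks).
#' @export
simulate_cohort <- function(annotation, config) {
  stopifnot(inherits(annotation, "cpg_annotation"))
  validate_sim_config(config)
  cfg <- config
  if (!identical(cfg$n_cpgs, annotation$config$n_cpgs) ||
      !identical(cfg$n_genes, annotation$config$n_genes))
    stop("annotation was built from a different configuration")
  set.seed(cfg$seed + 1000L)

  pr <- annotation$probes
  G <- nrow(pr)

  ## design: one control + one patient per set, plus configured extras
  rows <- list()
  for (i in seq_len(cfg$n_pairs)) {
    age_c <- stats::runif(1, 2, 40)
    sex <- sample(c("F", "M"), 1)
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sprintf("c%d", i), set = i, role = "control",
      age = age_c, sex = sex)
    if (i %in% cfg$extra_control_sets)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("c%d-2", i), set = i, role = "control",
        age = age_c + stats::rnorm(1, 0, 1), sex = sex)
    age_p <- age_c + stats::rnorm(1, 0, 2)
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sprintf("p%d", i), set = i, role = "patient",
      age = age_p, sex = sex)
    if (i %in% cfg$extra_patient_sets)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("p%d-2", i), set = i, role = "patient",
        age = age_p, sex = sex)
  }
  design <- do.call(rbind, rows)
  rownames(design) <- NULL
  S <- nrow(design)

  ## breakpoints (0 = no deletion)
  bp <- cfg$breakpoints
  if (is.null(bp)) bp <- stats::runif(cfg$n_pairs, 6e6, 35e6)
  names(bp) <- sprintf("p%d", seq_len(cfg$n_pairs))

  ## bimodal baseline beta
  lo <- stats::rbeta(G, cfg$beta_shape1, cfg$beta_shape2)
  hi <- stats::rbeta(G, cfg$beta_shape2, cfg$beta_shape1)
  pick_hi <- stats::runif(G) < 0.5
  base_beta <- ifelse(pick_hi, hi, lo)

  ## planted promoter effects (per-CpG signed delta, patients only)
  delta <- stats::setNames(numeric(G), pr$probe_id)
  planted_membership <- list()
  if (!is.null(cfg$planted_sets)) {
    for (j in seq_len(nrow(cfg$planted_sets))) {
      sid <- cfg$planted_sets$set[j]
      sgn <- if (cfg$planted_sets$direction[j] == "hypo") -1 else 1
      genes_j <- annotation$gene_sets[[sid]]
      cpgs_j <- pr$probe_id[!is.na(pr$promoter_gene) &
                              pr$promoter_gene %in% genes_j]
      delta[cpgs_j] <- delta[cpgs_j] + sgn * cfg$planted_sets$delta_beta[j]
      planted_membership[[sid]] <- cpgs_j
    }
  }

  ## planted-effect CpGs restart at intermediate methylation so the shift
  ## cannot clip (bivalent promoters sit at intermediate beta)
  has_effect <- delta != 0
  if (any(has_effect))
    base_beta[has_effect] <- stats::rbeta(sum(has_effect),
                                          cfg$beta_shape_effect,
                                          cfg$beta_shape_effect)

  ## per-CpG age slopes (0 unless age_drift configured)
  slope <- if (cfg$age_drift > 0)
    stats::rnorm(G, 0, cfg$age_drift) else numeric(G)

  clip <- function(b) pmin(pmax(b, 1e-6), 1 - 1e-6)
  is_pat <- design$role == "patient"
  mean_age <- mean(design$age)

  betas <- matrix(NA_real_, G, S, dimnames = list(pr$probe_id, design$sample_id))
  for (s in seq_len(S)) {
    b <- base_beta + slope * (design$age[s] - mean_age) / 10
    if (is_pat[s]) b <- b + delta
    if (cfg$beta_noise_sd > 0) b <- b + stats::rnorm(G, 0, cfg$beta_noise_sd)
    betas[, s] <- clip(b)
  }

  ## total intensities with lognormal noise; hemizygous halving in patients
  mu <- log(cfg$intensity_mean)
  total <- matrix(exp(mu + if (cfg$intensity_log_sd > 0)
    stats::rnorm(G * S, 0, cfg$intensity_log_sd) else 0),
    G, S, dimnames = dimnames(betas))
  on_5p <- pr$chrom == "chr5" & pr$pos < cfg$p_arm_end
  for (s in which(is_pat)) {
    set_i <- design$set[s]
    b_pos <- bp[[sprintf("p%d", set_i)]]
    if (b_pos > 0)
      total[on_5p & pr$pos < b_pos, s] <- total[on_5p & pr$pos < b_pos, s] / 2
  }

  meth <- total * betas
  unmeth <- total * (1 - betas)

  detp <- matrix(stats::runif(G * S, 0, 1e-4), G, S,
                 dimnames = dimnames(betas))
  n_fail <- floor(cfg$frac_detection_fail * G)
  if (n_fail > 0) {
    fail_probes <- sample.int(G, n_fail)
    fail_samples <- sample.int(S, n_fail, replace = TRUE)
    detp[cbind(fail_probes, fail_samples)] <- 0.5
  }

  truth <- list(breakpoints = bp, delta_beta = delta,
                planted_sets = cfg$planted_sets,
                planted_membership = planted_membership,
                bivalent_genes = annotation$bivalent_genes,
                mark_db = annotation$mark_db)

  out <- list(intensities = intensity_matrix(meth, unmeth, detp),
              design = design, truth = truth, betas = betas)
  class(out) <- "sim_cohort"
  out
}
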