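#' Configuration for the synthetic paired methylation cohort
#'
#' Bundles every tunable of the cohort generator into one validated object.
#' Defaults emulate an eight-pair blood study on an EPIC-style array scaled
#' down to a testable probe count: paired patient/control samples, bimodal
#' beta baselines, lognormal total intensities, hemizygous intensity halving
#' on the simulated chr5 p-arm up to a per-patient breakpoint, promoter
#' hypo-/hyper-methylation planted in chosen gene sets, and sporadic
#' detection-p failures.
#'
#' @param n_pairs number of patient/control sets (>= 2).
#' @param n_cpgs total number of CpG probes scattered over `chrom_lengths`
#'   (>= 100); probes deliberately seeded inside promoters count towards it.
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#'   Must contain `"chr5"`, the chromosome carrying simulated deletions.
#' @param p_arm_end bp coordinate of the chr5 centromere; positions below it
#'   form the p-arm (hg38 chr5 centromere is near 48.8 Mb).
#' @param breakpoints numeric vector (length `n_pairs`) of per-patient
#'   deletion breakpoints on chr5 in bp; `0` means no deletion. `NULL` draws
#'   them uniformly from \[6, 35\] Mb, the range spanned by short and long
#'   clinical deletions.
#' @param n_genes number of genes laid out across the chromosomes.
#' @param gene_body_len gene-body length in bp downstream of the promoter.
#' @param min_cpgs_per_promoter CpGs guaranteed inside every promoter window.
#' @param n_gene_sets,gene_set_size gene-set (category) database shape.
#' @param planted_sets data.frame with columns `set`, `direction`
#'   (`"hypo"`/`"hyper"`) and `delta_beta` in (0,1): gene sets whose promoter
#'   CpGs are shifted in patients. `NULL` plants nothing.
#' @param planted_off_chr5 keep planted-set genes off chr5 so genome-wide
#'   effects can be separated from the deleted region (the cohort this
#'   emulates shows category enrichment not driven by chr5).
#' @param bivalent_cooccurrence probability that an EZH2-marked CpG also
#'   carries each of SUZ12, H3K27me3, H3K4me2 and H3K4me3.
#' @param bivalent_background background rate of each mark off EZH2 anchors.
#' @param intensity_mean mean total (meth+unmeth) intensity per probe.
#' @param intensity_log_sd lognormal sigma of total intensity.
#' @param beta_noise_sd s.d. of per-sample additive beta noise.
#' @param beta_shape1,beta_shape2 Beta parameters of the low mode of the
#'   bimodal baseline; the high mode mirrors them.
#' @param beta_shape_effect symmetric Beta shape for planted-effect CpG
#'   baselines: effect CpGs start at intermediate methylation (as bivalent
#'   promoters do) so a +-delta shift stays inside (0,1) without clipping.
#' @param frac_detection_fail fraction of probes failing detection
#'   (p >= 0.01) in one random sample.
#' @param age_drift per-CpG age-slope scale; 0 disables age-correlated drift.
#'   Nonzero values make sample age a real source of methylation variance so
#'   covariate adjustment and PCA QC can be exercised against planted
#'   structure.
#' @param extra_control_sets,extra_patient_sets set indices that receive a
#'   second control (resp. patient) sample, mirroring cohorts where one set
#'   has an extra age-matched control or a technical replicate of the
#'   patient.
#' @param seed integer seed; all generator randomness derives from it.
#'
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_pairs = 8L,
                       n_cpgs = 20000L,
                       chrom_lengths = c(chr1 = 60e6, chr2 = 60e6, chr5 = 181e6),
                       p_arm_end = 48.8e6,
                       breakpoints = NULL,
                       n_genes = 150L,
                       gene_body_len = 20000,
                       min_cpgs_per_promoter = 5L,
                       n_gene_sets = 12L,
                       gene_set_size = 15L,
                       planted_sets = NULL,
                       planted_off_chr5 = TRUE,
                       bivalent_cooccurrence = 0.8,
                       bivalent_background = 0.02,
                       intensity_mean = 10000,
                       intensity_log_sd = 0.2,
                       beta_noise_sd = 0.03,
                       beta_shape1 = 5,
                       beta_shape2 = 45,
                       beta_shape_effect = 10,
                       frac_detection_fail = 0.001,
                       age_drift = 0,
                       extra_control_sets = integer(0),
                       extra_patient_sets = integer(0),
                       seed = 1L) {
  cfg <- list(
    n_pairs = as.integer(n_pairs), n_cpgs = as.integer(n_cpgs),
    chrom_lengths = chrom_lengths, p_arm_end = p_arm_end,
    breakpoints = breakpoints, n_genes = as.integer(n_genes),
    gene_body_len = gene_body_len,
    min_cpgs_per_promoter = as.integer(min_cpgs_per_promoter),
    n_gene_sets = as.integer(n_gene_sets),
    gene_set_size = as.integer(gene_set_size),
    planted_sets = planted_sets, planted_off_chr5 = isTRUE(planted_off_chr5),
    bivalent_cooccurrence = bivalent_cooccurrence,
    bivalent_background = bivalent_background,
    intensity_mean = intensity_mean, intensity_log_sd = intensity_log_sd,
    beta_noise_sd = beta_noise_sd,
    beta_shape1 = beta_shape1, beta_shape2 = beta_shape2,
    beta_shape_effect = beta_shape_effect,
    frac_detection_fail = frac_detection_fail,
    age_drift = age_drift,
    extra_control_sets = as.integer(extra_control_sets),
    extra_patient_sets = as.integer(extra_patient_sets),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_pairs >= 2L, cfg$n_cpgs >= 100L)
  if (length(cfg$chrom_lengths) == 0L || is.null(names(cfg$chrom_lengths)))
    stop("chrom_lengths must be a non-empty named vector")
  if (!"chr5" %in% names(cfg$chrom_lengths))
    stop("chrom_lengths must include chr5 (deletion chromosome)")
  if (!is.null(cfg$breakpoints)) {
    if (length(cfg$breakpoints) != cfg$n_pairs)
      stop("breakpoints must have one entry per pair")
    if (any(cfg$breakpoints < 0 | cfg$breakpoints > cfg$chrom_lengths[["chr5"]]))
      stop("breakpoints must lie within chr5")
  }
  if (!is.null(cfg$planted_sets)) {
    ps <- cfg$planted_sets
    stopifnot(is.data.frame(ps),
              all(c("set", "direction", "delta_beta") %in% names(ps)))
    if (!all(ps$direction %in% c("hypo", "hyper")))
      stop("planted directions must be 'hypo' or 'hyper'")
    if (any(ps$delta_beta <= 0 | ps$delta_beta >= 1))
      stop("delta_beta must be in (0, 1)")
  }
  stopifnot(cfg$frac_detection_fail >= 0, cfg$frac_detection_fail <= 1,
            cfg$intensity_log_sd >= 0, cfg$beta_noise_sd >= 0)
  invisible(cfg)
}
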