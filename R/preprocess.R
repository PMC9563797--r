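#' Construct an intensity matrix container
#'
#' Per-probe, per-sample methylated and unmethylated signals with detection
#' p-values, the raw input of the pipeline.
#'
#' @param meth,unmeth nonnegative numeric matrices (probes x samples) with
#'   matching dimnames.
#' @param detection_p matrix of detection p-values in \[0, 1\], same shape.
#' @return A list of class `"intensity_matrix"`.
#' @export
intensity_matrix <- function(meth, unmeth, detection_p) {
  stopifnot(is.matrix(meth), is.matrix(unmeth), is.matrix(detection_p),
            identical(dim(meth), dim(unmeth)),
            identical(dim(meth), dim(detection_p)))
  if (any(meth < 0) || any(unmeth < 0))
    stop("negative intensities are not allowed")
  if (any(detection_p < 0 | detection_p > 1))
    stop("detection p-values must lie in [0, 1]")
  if (is.null(rownames(meth)) || is.null(colnames(meth)))
    stop("meth must carry probe (row) and sample (column) names")
  structure(list(meth = meth, unmeth = unmeth, detection_p = detection_p),
            class = "intensity_matrix")
}

#' Filter probes by detection quality, SNP/cross-reactive flags and sex
#' chromosomes
#'
#' A probe is retained only if its detection p-value is below
#' `detection_threshold` in every sample, it is not flagged as
#' SNP-associated/cross-reactive, and it does not lie on a sex chromosome.
#' Probes absent from the annotation are removed and counted. The retained
#' set is the intersection of the three single-rule retained sets, so the
#' filter is idempotent.
#'
#' @param intensities an [intensity_matrix()].
#' @param annotation a `cpg_annotation` or a data.frame with columns
#'   `probe_id`, `snp_flag`, `sex_flag`.
#' @param detection_threshold detection p cutoff, default 0.01 (probes must
#'   be below it in all samples).
#' @return A list with `retained` (character vector of probe ids, in input
#'   order) and `removed` (named counts per rule: `not_annotated`,
#'   `detection`, `snp`, `sex_chromosome`; a probe can appear under several
#'   rules).
#' @export
filter_probes <- function(intensities, annotation, detection_threshold = 0.01) {
  stopifnot(inherits(intensities, "intensity_matrix"),
            detection_threshold > 0, detection_threshold < 1)
  ann <- if (inherits(annotation, "cpg_annotation")) annotation$probes else annotation
  stopifnot(all(c("probe_id", "snp_flag", "sex_flag") %in% names(ann)))

  ids <- rownames(intensities$meth)
  annotated <- ids %in% ann$probe_id
  pass_det <- rowSums(intensities$detection_p >= detection_threshold) == 0

  idx <- match(ids, ann$probe_id)
  snp <- ifelse(is.na(idx), FALSE, ann$snp_flag[idx])
  sex <- ifelse(is.na(idx), FALSE, ann$sex_flag[idx])

  keep <- annotated & pass_det & !snp & !sex
  retained <- ids[keep]
  if (length(retained) == 0L)
    stop("no probes retained after filtering")
  list(retained = retained,
       removed = c(not_annotated = sum(!annotated),
                   detection = sum(!pass_det),
                   snp = sum(snp, na.rm = TRUE),
                   sex_chromosome = sum(sex, na.rm = TRUE)))
}

#' Beta values from intensities
#'
#' `beta = meth / (meth + unmeth + offset)`, the standard Illumina
#' convention with offset 100 to stabilise low-intensity probes.
#'
#' @param intensities an [intensity_matrix()].
#' @param offset nonnegative regularising offset (default 100).
#' @return A numeric matrix of betas with attribute `"offset"` recording the
#'   provenance.
#' @export
compute_beta <- function(intensities, offset = 100) {
  stopifnot(inherits(intensities, "intensity_matrix"), offset >= 0)
  denom <- intensities$meth + intensities$unmeth + offset
  if (offset == 0 && any(denom == 0))
    stop("offset = 0 with zero total intensity gives 0/0")
  beta <- intensities$meth / denom
  attr(beta, "offset") <- offset
  beta
}

#' M-values (logit2 of beta)
#'
#' `M = log2(b / (1 - b))` with betas clipped to
#' `[clip_eps, 1 - clip_eps]` so the logit is always finite.
#'
#' @param beta numeric matrix of betas.
#' @param clip_eps clipping bound in (0, 0.5), default `1e-6`.
#' @return Matrix of M-values with attribute `"clip_eps"`.
#' @export
compute_m <- function(beta, clip_eps = 1e-6) {
  stopifnot(clip_eps > 0, clip_eps < 0.5)
  b <- pmin(pmax(beta, clip_eps), 1 - clip_eps)
  m <- log2(b / (1 - b))
  attr(m, "clip_eps") <- clip_eps
  attr(m, "offset") <- attr(beta, "offset")
  m
}

#' Total signal (methylated + unmethylated) per probe and sample
#'
#' The copy-number proxy used by the deletion caller.
#'
#' @param intensities an [intensity_matrix()].
#' @return Numeric matrix of sums.
#' @export
total_signal <- function(intensities) {
  stopifnot(inherits(intensities, "intensity_matrix"))
  intensities$meth + intensities$unmeth
}
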