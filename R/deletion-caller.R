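#' Log2 ratio of a patient's total signal to the control mean
#'
#' For each CpG on the requested chromosome,
#' `log2(patient_total / mean(control_totals))`: the copy-number proxy a
#' hemizygous deletion drives to about -1.
#'
#' @param total matrix of total (meth + unmeth) signals, probes x samples.
#' @param patient patient sample id (column of `total`).
#' @param controls control sample ids (>= 1).
#' @param annotation `cpg_annotation` or data.frame with `probe_id`,
#'   `chrom`, `pos`.
#' @param chromosome chromosome to extract, e.g. `"chr5"`.
#' @param max_pos optional upper bound on position (restrict to the p-arm by
#'   passing the centromere coordinate).
#' @return A data.frame of class `"ratio_track"` (`probe_id`, `pos`,
#'   `ratio`), sorted by position. Probes whose control mean is zero are an
#'   error, with the offending ids attached to the condition.
#' @export
log_ratio_track <- function(total, patient, controls, annotation,
                            chromosome = "chr5", max_pos = NULL) {
  ann <- if (inherits(annotation, "cpg_annotation")) annotation$probes else annotation
  stopifnot(patient %in% colnames(total), all(controls %in% colnames(total)),
            length(controls) >= 1L)
  ann <- ann[ann$chrom == chromosome & ann$probe_id %in% rownames(total), ]
  if (!is.null(max_pos)) ann <- ann[ann$pos < max_pos, ]
  ann <- ann[order(ann$pos), ]
  if (nrow(ann) == 0L) stop("no probes on ", chromosome)
  ctl <- rowMeans(total[ann$probe_id, controls, drop = FALSE])
  if (any(ctl == 0)) {
    cond <- simpleError("zero control mean at some probes")
    cond$flagged_probes <- ann$probe_id[ctl == 0]
    stop(cond)
  }
  out <- data.frame(probe_id = ann$probe_id, pos = ann$pos,
                    ratio = log2(total[ann$probe_id, patient] / ctl),
                    row.names = NULL)
  class(out) <- c("ratio_track", "data.frame")
  out
}

#' Loess-smooth a ratio track
#'
#' Local quadratic regression of the log2 ratio on position with tricube
#' weights over the `span * N` nearest neighbours (gaussian family, no
#' robustness iterations), evaluated exactly at every observed CpG position.
#'
#' @param track a [log_ratio_track()].
#' @param span loess span, default 0.05.
#' @param degree local polynomial degree, default 2.
#' @return The track with a `smoothed` column added; `span` recorded as an
#'   attribute.
#' @export
loess_smooth <- function(track, span = 0.05, degree = 2) {
  stopifnot(inherits(track, "ratio_track"))
  n <- nrow(track)
  if (n < 10L) stop("need at least 10 points to smooth")
  if (span * n < 4) stop("span * N must give at least 4 points per local fit")
  fit <- stats::loess(ratio ~ pos, data = track, span = span, degree = degree,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  track$smoothed <- stats::predict(fit, newdata = track)
  attr(track, "span") <- span
  track
}

#' Call a deletion breakpoint from a smoothed ratio track
#'
#' The breakpoint is the position farthest out on the arm (lowest
#' coordinate, telomere at 0) that is beyond `min_pos` (the telomeric end is
#' too noisy to call) and whose smoothed signal has recovered above
#' `threshold`. Three regimes:
#' * the track starts below `threshold` and recovers: a deletion call at the
#'   recovery point;
#' * the track never exceeds `threshold` at an eligible position: the
#'   deletion extends past the scanned arm, breakpoint `"none detected"`
#'   (`NA`);
#' * the track never drops below `threshold` before the first eligible
#'   position: no deletion; the first eligible position is reported with
#'   `no_deletion = TRUE` rather than as a ~`min_pos` call, since the rule
#'   presumes a deletion exists.
#'
#' Later transient dips below `threshold` (interstitial-loss-like) are
#' logged in `later_dips`.
#'
#' @param track a smoothed track from [loess_smooth()].
#' @param min_pos lowest callable position (default 5e6).
#' @param threshold smoothed log2-ratio recovery threshold (default -0.25).
#' @param patient optional patient id recorded in the call.
#' @return A list of class `"deletion_call"`: `patient`, `breakpoint` (bp or
#'   `NA`), `size` (== breakpoint; telomere at 0), `no_deletion`,
#'   `later_dips` (positions), `params`.
#' @export
call_breakpoint <- function(track, min_pos = 5e6, threshold = -0.25,
                            patient = NA_character_) {
  stopifnot(inherits(track, "ratio_track"), "smoothed" %in% names(track))
  if (nrow(track) == 0L) stop("empty track")
  sm <- track$smoothed
  pos <- track$pos
  eligible <- pos > min_pos
  above <- sm > threshold
  idx <- which(eligible & above)
  if (length(idx) == 0L) {
    bp <- NA_real_
    no_del <- FALSE
    later <- numeric(0)
  } else {
    i <- idx[1]
    bp <- pos[i]
    no_del <- !any(sm[seq_len(i)] <= threshold)
    later <- pos[-seq_len(i)][sm[-seq_len(i)] <= threshold]
  }
  structure(list(patient = patient, breakpoint = bp, size = bp,
                 no_deletion = no_del, later_dips = later,
                 params = list(span = attr(track, "span"),
                               min_pos = min_pos, threshold = threshold)),
            class = "deletion_call")
}

#' Call 5p deletion breakpoints for every patient in a cohort
#'
#' Runs [log_ratio_track()], [loess_smooth()] and [call_breakpoint()] for
#' each patient sample against all controls.
#'
#' @param intensities an [intensity_matrix()] (filtered or not).
#' @param design paired design data.frame.
#' @param annotation probe annotation.
#' @param chromosome,max_pos,span,min_pos,threshold caller parameters;
#'   `max_pos` defaults to the annotation's `p_arm_end` when available.
#' @param probes optional retained-probe universe.
#' @return A data.frame with one row per patient sample: `patient`, `set`,
#'   `breakpoint`, `size`, `no_deletion`; the smoothed tracks are attached
#'   as attribute `"tracks"` (named list).
#' @export
call_deletions <- function(intensities, design, annotation,
                           chromosome = "chr5", max_pos = NULL,
                           span = 0.05, min_pos = 5e6, threshold = -0.25,
                           probes = NULL) {
  if (is.null(max_pos) && inherits(annotation, "cpg_annotation"))
    max_pos <- annotation$p_arm_end
  total <- total_signal(intensities)
  if (!is.null(probes)) total <- total[probes, , drop = FALSE]
  controls <- design$sample_id[design$role == "control"]
  patients <- design$sample_id[design$role == "patient"]
  tracks <- list()
  rows <- lapply(patients, function(pt) {
    tr <- log_ratio_track(total, pt, controls, annotation, chromosome, max_pos)
    tr <- loess_smooth(tr, span)
    tracks[[pt]] <<- tr
    cl <- call_breakpoint(tr, min_pos, threshold, patient = pt)
    data.frame(patient = pt, set = design$set[design$sample_id == pt][1],
               breakpoint = cl$breakpoint, size = cl$size,
               no_deletion = cl$no_deletion)
  })
  out <- do.call(rbind, rows)
  attr(out, "tracks") <- tracks
  out
}
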