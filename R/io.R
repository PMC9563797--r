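#' Read a GMT gene-set file
#'
#' GMT is line-oriented: set id, description, then member ids, tab-separated.
#'
#' @param path file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) p[-(1:2)]),
                  vapply(parts, `[`, "", 1L))
}

#' Write a GMT gene-set file
#'
#' @param sets named list of character vectors.
#' @param path file path.
#' @param descriptions optional character vector of descriptions (recycled
#'   `"na"` otherwise).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(id, desc, members)
    paste(c(id, desc, members), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(unname(lines), path)
}

#' Write a simulated cohort to plain-text files
#'
#' Produces the pipeline's on-disk dialects: a long intensity table
#' (probe_id, sample_id, meth, unmeth, detection_p), the probe annotation
#' (TSV) plus promoter/body intervals (BED, 0-based half-open as the format
#' requires), gene sets and CpG category databases (GMT), the paired design
#' (TSV) and the truth record (TSV).
#'
#' @param cohort a [simulate_cohort()] result.
#' @param annotation the matching [make_annotation()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of files written.
#' @export
write_cohort <- function(cohort, annotation, dir) {
  stopifnot(inherits(cohort, "sim_cohort"),
            inherits(annotation, "cpg_annotation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  int <- cohort$intensities
  long <- data.frame(
    probe_id = rep(rownames(int$meth), ncol(int$meth)),
    sample_id = rep(colnames(int$meth), each = nrow(int$meth)),
    meth = as.vector(int$meth),
    unmeth = as.vector(int$unmeth),
    detection_p = as.vector(int$detection_p))
  files <- c(
    intensities = file.path(dir, "intensities.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    intervals = file.path(dir, "gene_intervals.bed"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    categories = file.path(dir, "cpg_categories.gmt"),
    design = file.path(dir, "design.tsv"),
    truth = file.path(dir, "truth.tsv"))
  wt <- function(x, f) utils::write.table(
    x, f, sep = "\t", quote = FALSE, row.names = FALSE)
  wt(long, files["intensities"])
  wt(annotation$probes, files["annotation"])
  g <- annotation$genes
  bed <- rbind(
    data.frame(chrom = g$chrom, start = g$promoter_start - 1L,
               end = g$promoter_end - 1L, name = paste0(g$gene, "_promoter")),
    data.frame(chrom = g$chrom, start = g$body_start - 1L,
               end = g$body_end - 1L, name = paste0(g$gene, "_body")))
  utils::write.table(bed, files["intervals"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_gmt(annotation$gene_sets, files["gene_sets"])
  write_gmt(annotation$category_db, files["categories"])
  wt(cohort$design, files["design"])
  wt(data.frame(probe_id = names(cohort$truth$delta_beta),
                delta_beta = unname(cohort$truth$delta_beta)),
     files["truth"])
  invisible(files)
}

#' Read a long intensity table back into an intensity matrix
#'
#' @param path TSV with columns probe_id, sample_id, meth, unmeth,
#'   detection_p.
#' @return An [intensity_matrix()].
#' @export
read_intensities <- function(path) {
  long <- utils::read.delim(path, stringsAsFactors = FALSE)
  probes <- unique(long$probe_id)
  samples <- unique(long$sample_id)
  shape <- function(col) {
    m <- matrix(NA_real_, length(probes), length(samples),
                dimnames = list(probes, samples))
    m[cbind(match(long$probe_id, probes), match(long$sample_id, samples))] <-
      long[[col]]
    m
  }
  intensity_matrix(shape("meth"), shape("unmeth"), shape("detection_p"))
}
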