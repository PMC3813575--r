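#' Reads per kilobase of exon per million mapped reads
#'
#' `RPKM = 1e9 * count / (exon_length_nt * total_mapped_reads)`.
#' All three arguments recycle to a common length.
#'
#' @param count non-negative read count(s) on the exon.
#' @param exon_length_nt exon length in nucleotides (> 0).
#' @param total_mapped_reads per-sample library size in reads (> 0).
#' @export
exon_rpkm <- function(count, exon_length_nt, total_mapped_reads) {
  if (any(exon_length_nt <= 0)) stop("exon length must be positive")
  if (any(total_mapped_reads <= 0)) stop("library size must be positive")
  if (any(count < 0)) stop("counts must be non-negative")
  1e9 * count / (exon_length_nt * total_mapped_reads)
}

#' Rescaled exon expression index
#'
#' Divides each exon's RPKM by the mean RPKM over the exons of the same gene
#' in the same sample, so the indexes of a (sample, gene) average exactly 1
#' and carry relative (splicing) rather than overall expression information.
#' When the mean is 0 all indexes of that (sample, gene) are set to `NA` and
#' flagged.  Single-exon genes always yield index 1 and carry no splicing
#' signal; they are skipped by the sQTL scan.
#'
#' @param rpkm numeric vector (one sample) or matrix (exons x samples) of the
#'   RPKMs of one gene's exons.
#' @return object of the same shape with attribute `flagged` (logical per
#'   sample: zero-mean cases).
#' @export
rescale_exon_index <- function(rpkm) {
  if (is.matrix(rpkm)) {
    m <- colMeans(rpkm)
    flagged <- m == 0
    idx <- sweep(rpkm, 2, ifelse(flagged, NA_real_, m), "/")
  } else {
    m <- mean(rpkm)
    flagged <- m == 0
    idx <- if (flagged) rep(NA_real_, length(rpkm)) else rpkm / m
  }
  attr(idx, "flagged") <- flagged
  idx
}

#' Inverse-variance observation weights
#'
#' The weight of an observation is the reciprocal of the sample variance of
#' the trait values in its cell — per dataset group (`per_group`, the gene
#' expression models) or per group-by-exon cell (`per_group_exon`, the
#' splicing models) — then normalised to mean 1 (the proportionality constant
#' of inverse-variance weighting is arbitrary; the normalisation is recorded).
#' Cells with (near-)zero variance get a floored variance of
#' `1e-8 * var(values)` and are flagged rather than producing infinite
#' weights.
#'
#' @param values numeric trait vector (one value per observation).
#' @param group factor/vector: the observation's dataset group.
#' @param exon factor/vector of exon labels, required for `per_group_exon`.
#' @param mode `"per_group"` or `"per_group_exon"`.
#' @return data frame with columns `weight` (positive, mean 1), `cell` (the
#'   variance cell used) and `flagged` (variance floor applied); attribute
#'   `normalization = "mean_1"`.
#' @export
compute_weights <- function(values, group, exon = NULL,
                            mode = c("per_group", "per_group_exon")) {
  mode <- match.arg(mode)
  stopifnot(length(group) == length(values))
  cell <- if (mode == "per_group_exon") {
    if (is.null(exon)) stop("exon labels required for per_group_exon weights")
    stopifnot(length(exon) == length(values))
    interaction(group, exon, drop = TRUE, sep = ":")
  } else factor(group)
  v <- tapply(values, cell, stats::var)
  if (any(is.na(v)))
    stop("each variance cell needs >= 2 observations: ",
         paste(names(v)[is.na(v)], collapse = ", "))
  floorv <- 1e-8 * stats::var(values)
  if (floorv <= 0) floorv <- 1e-12
  flagged_cell <- v < floorv
  v[flagged_cell] <- floorv
  w <- 1 / v[as.character(cell)]
  w <- w / mean(w)
  out <- data.frame(weight = unname(w), cell = as.character(cell),
                    flagged = unname(flagged_cell[as.character(cell)]),
                    stringsAsFactors = FALSE)
  attr(out, "normalization") <- "mean_1"
  out
}
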