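#' Classify a cis SNP position into a gene-anchored genomic region
#'
#' Partitions the flanked gene territory into seven labels: `U1-20K`,
#' `U0-1K`, `5'UTR`, `CDS`, `3'UTR`, `D0-1K`, `D1-20K`.  "Upstream" and
#' "downstream" follow the gene's strand (upstream = 5' side), so for a
#' minus-strand gene positions beyond the genomic end coordinate are
#' upstream.  Inside the transcript, positions genomically between
#' `cds_start` and `cds_end` fall in the `CDS` bucket (coding exons and the
#' introns between them), and positions outside the CDS span fall in the
#' strand-appropriate UTR bucket (UTR exons and introns between them) —
#' this intron policy keeps the assignment an exact partition.  Non-coding
#' genes bypass the UTR/CDS subdivision: inside-transcript positions get the
#' label `transcript`.
#'
#' @param pos SNP position(s), 1-based.
#' @param gene one row of a gene-model data frame (`chrom`, `strand`,
#'   `tx_start`, `tx_end`, `cds_start`, `cds_end`, `coding`).
#' @param flank the cis flank (positions farther than this are an error:
#'   the SNP must be cis to the gene).
#' @return character vector of region labels.
#' @export
classify_region <- function(pos, gene, flank = 20000) {
  up_is_left <- gene$strand == "+"
  out <- character(length(pos))
  for (i in seq_along(pos)) {
    p <- pos[i]
    if (p < gene$tx_start - flank || p > gene$tx_end + flank)
      stop("position ", p, " is not cis to gene ", gene$gene_id)
    if (p < gene$tx_start) {
      d <- gene$tx_start - p
      side_up <- up_is_left
    } else if (p > gene$tx_end) {
      d <- p - gene$tx_end
      side_up <- !up_is_left
    } else {
      if (!isTRUE(gene$coding)) { out[i] <- "transcript"; next }
      out[i] <- if (p < gene$cds_start) {
        if (up_is_left) "5'UTR" else "3'UTR"
      } else if (p > gene$cds_end) {
        if (up_is_left) "3'UTR" else "5'UTR"
      } else "CDS"
      next
    }
    band <- if (d <= 1000) "0-1K" else "1-20K"
    out[i] <- paste0(if (side_up) "U" else "D", band)
  }
  out
}

#' Region labels in canonical 5'-to-3' order
#' @export
region_levels <- function()
  c("U1-20K", "U0-1K", "5'UTR", "CDS", "3'UTR", "D0-1K", "D1-20K")

#' QTL SNP density index per genomic region
#'
#' `index_r = (count_r / total) / avg_len_kb_r`: the proportion of QTL SNPs
#' falling in region class `r`, divided by the class's average length in
#' kilobases.  Zero-length classes yield `NA`.
#'
#' @param counts named integer vector of SNP counts per region.
#' @param avg_len_kb named numeric vector of average region lengths (kb),
#'   aligned with `counts`.
#' @return named numeric vector of density indexes.
#' @export
density_index <- function(counts, avg_len_kb) {
  stopifnot(length(counts) == length(avg_len_kb))
  total <- sum(counts)
  if (total <= 0) stop("total SNP count must be positive")
  idx <- (counts / total) / avg_len_kb
  idx[!is.finite(avg_len_kb) | avg_len_kb <= 0] <- NA_real_
  idx
}

#' Per-SNP region assignment and per-region density summary
#'
#' Maps every called cis SNP onto its host gene's regions and summarises
#' counts, proportions, average region lengths and density indexes.  The
#' UTR/CDS subdivision (and hence rows `5'UTR`, `CDS`, `3'UTR`) is computed
#' over protein-coding genes; SNPs on non-coding genes are reported in a
#' separate `transcript` row excluded from the coding-gene analysis columns.
#' Average lengths use the genomic spans consistent with the intron policy
#' of [classify_region()]; the flank classes have fixed lengths 1 kb
#' (`U0-1K`, `D0-1K`) and 19 kb (`U1-20K`, `D1-20K`) by construction.
#'
#' @param calls data frame with `snp_id` and `gene_id` (cis calls).
#' @param geno a [genotype_matrix()].
#' @param gene_models gene-model table.
#' @param flank cis flank (nt).
#' @return list: `per_snp` (calls plus `region`), `summary` (region, count,
#'   proportion, avg_len_kb, density_index).
#' @export
region_summary <- function(calls, geno, gene_models, flank = 20000) {
  stopifnot(all(c("snp_id", "gene_id") %in% names(calls)))
  if (nrow(calls) == 0)
    return(list(per_snp = cbind(calls, region = character(0)),
                summary = NULL))
  pos <- geno$info$pos[match(calls$snp_id, geno$info$snp_id)]
  region <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    gene <- gene_models[gene_models$gene_id == calls$gene_id[i], ]
    region[i] <- classify_region(pos[i], gene, flank = flank)
  }
  per_snp <- cbind(calls, region = region, stringsAsFactors = FALSE)

  coding_genes <- gene_models[gene_models$coding &
                                gene_models$gene_id %in% calls$gene_id, ]
  lev <- region_levels()
  kb <- function(a, b) (b - a + 1) / 1000
  avg_len <- c(
    `U1-20K` = 19, `U0-1K` = 1,
    `5'UTR` = mean(ifelse(coding_genes$strand == "+",
                          kb(coding_genes$tx_start, coding_genes$cds_start - 1),
                          kb(coding_genes$cds_end + 1, coding_genes$tx_end))),
    CDS = mean(kb(coding_genes$cds_start, coding_genes$cds_end)),
    `3'UTR` = mean(ifelse(coding_genes$strand == "+",
                          kb(coding_genes$cds_end + 1, coding_genes$tx_end),
                          kb(coding_genes$tx_start, coding_genes$cds_start - 1))),
    `D0-1K` = 1, `D1-20K` = 19)
  in_coding <- region %in% lev
  counts <- table(factor(region[in_coding], levels = lev))
  summ <- data.frame(region = lev, count = as.integer(counts),
                     proportion = as.numeric(counts) / max(1, sum(counts)),
                     avg_len_kb = as.numeric(avg_len[lev]),
                     stringsAsFactors = FALSE)
  summ$density_index <- if (sum(counts) > 0)
    as.numeric(density_index(counts, avg_len[lev])) else NA_real_
  if (any(!in_coding))
    summ <- rbind(summ, data.frame(region = "transcript",
                                   count = sum(!in_coding), proportion = NA,
                                   avg_len_kb = NA, density_index = NA))
  list(per_snp = per_snp, summary = summ)
}
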