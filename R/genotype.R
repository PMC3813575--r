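#' Construct a genotype matrix object
#'
#' Container for additively coded bi-allelic genotypes: an integer matrix of
#' reference-allele counts (0/1/2, `NA` = undetermined) with SNPs in rows and
#' cell lines in columns, plus a SNP information table.
#'
#' @param codes integer/numeric matrix (SNPs x cell lines), values in
#'   \{0, 1, 2, NA\}; row names are SNP ids, column names cell-line ids.
#' @param info data frame with one row per SNP: `snp_id`, `chrom`, `pos`
#'   (1-based), `ref` (reference allele), optionally `alt`.
#' @return object of class `"geno_matrix"`.
#' @export
genotype_matrix <- function(codes, info) {
  codes <- as.matrix(codes)
  stopifnot(nrow(codes) == nrow(info),
            all(c("snp_id", "chrom", "pos", "ref") %in% names(info)))
  bad <- !(codes %in% c(0L, 1L, 2L) | is.na(codes))
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  if (any(info$pos < 0)) stop("SNP positions must be non-negative")
  rownames(codes) <- info$snp_id
  structure(list(codes = codes, info = as.data.frame(info)),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("Genotype matrix:", nrow(x$codes), "SNPs x", ncol(x$codes),
      "cell lines;", sum(is.na(x$codes)), "missing calls\n")
  cat("Chromosomes:", paste(unique(x$info$chrom), collapse = ", "), "\n")
  invisible(x)
}

#' Encode bi-allelic genotype calls as reference-allele counts
#'
#' Each call (an unordered allele pair such as `"A/C"`) becomes the number of
#' reference alleles it contains: 0, 1 or 2.  Undetermined calls (any allele
#' outside \{A, C, G, T\} matching neither declared allele, e.g. `"N/N"`) are
#' set to `NA` and are never imputed; the affected cell lines are simply
#' excluded from that SNP's model fits downstream.  SNPs on the mitochondrial
#' chromosome are dropped.
#'
#' @param calls character matrix (SNPs x cell lines) of `"X/Y"` calls.
#' @param info SNP table as in [genotype_matrix()]; must also contain `alt`
#'   (the non-reference allele).
#' @param mito_chroms chromosome names treated as mitochondrial.
#' @return a [genotype_matrix()] without mitochondrial SNPs.
#' @export
encode_genotypes <- function(calls, info,
                             mito_chroms = c("chrM", "chrMT", "M", "MT")) {
  calls <- as.matrix(calls)
  stopifnot(nrow(calls) == nrow(info), "alt" %in% names(info))
  keep <- !(info$chrom %in% mito_chroms)
  calls <- calls[keep, , drop = FALSE]
  info <- info[keep, , drop = FALSE]
  codes <- matrix(NA_integer_, nrow(calls), ncol(calls),
                  dimnames = dimnames(calls))
  for (i in seq_len(nrow(calls))) {
    al <- strsplit(calls[i, ], "/", fixed = TRUE)
    a1 <- vapply(al, `[`, "", 1L)
    a2 <- vapply(al, `[`, "", 2L)
    valid <- c(info$ref[i], info$alt[i])
    undet <- !(a1 %in% c(valid, "N", ".")) | !(a2 %in% c(valid, "N", "."))
    foreign <- undet & (a1 %in% c("A", "C", "G", "T")) &
      (a2 %in% c("A", "C", "G", "T"))
    if (any(foreign))
      stop("SNP ", info$snp_id[i], ": call with allele outside ",
           info$ref[i], "/", info$alt[i], " in cell line(s) ",
           paste(colnames(calls)[foreign], collapse = ", "))
    ok <- (a1 %in% valid) & (a2 %in% valid)
    codes[i, ok] <- (a1[ok] == info$ref[i]) + (a2[ok] == info$ref[i])
  }
  genotype_matrix(codes, info)
}

#' Composite-LD correlation test for a SNP pair
#'
#' The composite linkage-disequilibrium correlation for unphased diploid data
#' is estimated as the Pearson correlation `r` of the 0/1/2 genotype codes
#' over the cell lines where both SNPs are observed, and tested with
#' \eqn{t = r\sqrt{(m-2)/(1-r^2)}} against a t distribution with `m - 2`
#' degrees of freedom (two-sided), `m` being the number of jointly observed
#' lines.
#'
#' @param codes_a,codes_b genotype code vectors of the two SNPs.
#' @return list `r`, `t`, `p`, `m`, `degenerate` (TRUE when either SNP has
#'   zero variance on the joint lines — `r` undefined; such pairs are treated
#'   as dependent by [ld_prune()]).
#' @export
composite_ld_test <- function(codes_a, codes_b) {
  stopifnot(length(codes_a) == length(codes_b))
  ok <- !is.na(codes_a) & !is.na(codes_b)
  m <- sum(ok)
  if (m < 3) stop("need >= 3 jointly observed cell lines")
  a <- codes_a[ok]; b <- codes_b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0)
    return(list(r = NA_real_, t = NA_real_, p = NA_real_, m = m,
                degenerate = TRUE))
  r <- stats::cor(a, b)
  if (abs(r) >= 1) {
    t <- sign(r) * Inf; p <- 0
  } else {
    t <- r * sqrt((m - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), df = m - 2)
  }
  list(r = r, t = t, p = p, m = m, degenerate = FALSE)
}

#' Prune cis SNP subsets to composite-LD independence
#'
#' Within each gene's cis SNP subset, all pairwise composite-LD tests are
#' computed (pairwise-complete observations), p-values are
#' Bonferroni-adjusted by the number of pairs tested within the subset, and
#' SNPs are retained greedily in ascending genomic position: a SNP is dropped
#' iff its adjusted p-value against an already-retained SNP is below `alpha`
#' (or the pair is degenerate, which is treated as dependent).  The result is
#' a subset in which no retained pair is significantly correlated, and the
#' operation is idempotent.
#'
#' @param geno a [genotype_matrix()].
#' @param cis_sets named list: gene id -> character vector of cis SNP ids
#'   (see [find_cis_pairs()]).
#' @param alpha significance cutoff on the Bonferroni-adjusted p-value.
#' @return object of class `"pruned_set"`: list with `kept` (gene -> retained
#'   SNP ids), `audit` (per-gene data frame of the tested pairs: `snp_a`,
#'   `snp_b`, `r`, `p`, `p_adj`, `dropped_b`), `alpha`.
#' @export
ld_prune <- function(geno, cis_sets, alpha = 0.01) {
  stopifnot(inherits(geno, "geno_matrix"))
  kept <- list(); audit <- list()
  for (g in names(cis_sets)) {
    snps <- cis_sets[[g]]
    if (length(snps) == 0) { kept[[g]] <- character(0); next }
    miss <- setdiff(snps, geno$info$snp_id)
    if (length(miss)) stop("unknown SNP id(s): ", paste(miss, collapse = ", "))
    ord <- order(geno$info$pos[match(snps, geno$info$snp_id)],
                 match(snps, geno$info$snp_id))
    snps <- snps[ord]
    if (length(snps) == 1) { kept[[g]] <- snps; next }
    n_pairs <- choose(length(snps), 2)
    retained <- snps[1]
    rows <- list()
    for (s in snps[-1]) {
      drop_s <- FALSE
      for (t in retained) {
        lt <- composite_ld_test(geno$codes[s, ], geno$codes[t, ])
        p_adj <- min(1, lt$p * n_pairs)
        dep <- lt$degenerate || (is.finite(p_adj) && p_adj < alpha)
        rows[[length(rows) + 1]] <- data.frame(
          gene = g, snp_a = t, snp_b = s, r = lt$r, p = lt$p, p_adj = p_adj,
          dropped_b = dep, stringsAsFactors = FALSE)
        if (dep) { drop_s <- TRUE; break }
      }
      if (!drop_s) retained <- c(retained, s)
    }
    kept[[g]] <- retained
    audit[[g]] <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  structure(list(kept = kept,
                 audit = do.call(rbind, audit[!vapply(audit, is.null, TRUE)]),
                 alpha = alpha),
            class = "pruned_set")
}

#' @export
print.pruned_set <- function(x, ...) {
  cat("Pruned cis SNP sets for", length(x$kept), "genes;",
      sum(lengths(x$kept)), "SNPs retained (alpha =", x$alpha, ")\n")
  invisible(x)
}

#' Read / write the package's genotype TSV layout
#'
#' The genotype TSV has SNPs in rows and cell lines in columns with values
#' 0/1/2/NA; the companion position table has columns
#' `chrom, pos, snp_id, ref, alt`.
#' @param codes_file,info_file paths.
#' @return a [genotype_matrix()].
#' @export
read_genotype_tsv <- function(codes_file, info_file) {
  codes <- as.matrix(utils::read.table(codes_file, header = TRUE, sep = "\t",
                                       row.names = 1, check.names = FALSE))
  info <- utils::read.table(info_file, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  genotype_matrix(codes[info$snp_id, , drop = FALSE], info)
}

#' @rdname read_genotype_tsv
#' @param geno a [genotype_matrix()].
#' @export
write_genotype_tsv <- function(geno, codes_file, info_file) {
  utils::write.table(cbind(snp_id = rownames(geno$codes),
                           as.data.frame(geno$codes)),
                     codes_file, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(geno$info, info_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(geno)
}

#' Read bi-allelic genotypes from a VCF file
#'
#' Bi-allelic records only; the GT field is converted to the count of
#' REFERENCE alleles (`0/0` -> 2, `0/1` -> 1, `1/1` -> 0, missing -> NA).
#' Requires the suggested package `vcfR`.
#'
#' @param file path to a VCF.
#' @return a [genotype_matrix()].
#' @export
read_genotype_vcf <- function(file) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package")
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  bi <- !grepl(",", fix$ALT, fixed = TRUE)
  gt <- vcfR::extract.gt(v, element = "GT")[bi, , drop = FALSE]
  fix <- fix[bi, , drop = FALSE]
  alt_count <- function(s) {
    al <- strsplit(sub("\\|", "/", s), "/", fixed = FALSE)
    vapply(al, function(x) {
      if (length(x) != 2 || any(x == ".") || any(is.na(x))) return(NA_integer_)
      sum(x == "1")
    }, 1L)
  }
  codes <- 2L - t(apply(gt, 1, alt_count))
  if (ncol(gt) == 1) codes <- matrix(codes, ncol = 1, dimnames = dimnames(gt))
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID)
  info <- data.frame(snp_id = ids, chrom = fix$CHROM,
                     pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
                     stringsAsFactors = FALSE)
  dimnames(codes) <- list(ids, colnames(gt))
  encode_ok <- !(info$chrom %in% c("chrM", "chrMT", "M", "MT"))
  genotype_matrix(codes[encode_ok, , drop = FALSE],
                  info[encode_ok, , drop = FALSE])
}
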