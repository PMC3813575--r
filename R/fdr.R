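#' Permute genotypes across cell lines
#'
#' Builds `k` permuted copies of a genotype matrix by shuffling the cell-line
#' columns (codes and missingness move together).  Permutation is at the
#' cell-line level, not the sample level, so when the permuted matrix is used
#' in a scan all replicate samples of one line still share a common — but
#' wrong — genotype, preserving the subject dependence structure under the
#' null.  Optionally the shuffle is restricted to within strata (e.g.
#' population).
#'
#' @param geno a [genotype_matrix()].
#' @param k number of permutations (>= 1).
#' @param seed integer seed; the `k` permutations are drawn consecutively.
#' @param strata optional factor/vector over the cell lines (in column order
#'   or named by cell line); permutation then happens within each stratum.
#' @return list of `k` [genotype_matrix()] objects.
#' @export
permute_genotypes <- function(geno, k, seed, strata = NULL) {
  stopifnot(inherits(geno, "geno_matrix"), k >= 1)
  nl <- ncol(geno$codes)
  if (!is.null(strata)) {
    if (!is.null(names(strata))) strata <- strata[colnames(geno$codes)]
    stopifnot(length(strata) == nl)
    strata <- factor(strata)
  }
  restore <- .local_seed(as.integer(seed))
  on.exit(restore())
  out <- vector("list", k)
  for (i in seq_len(k)) {
    perm <- if (is.null(strata)) sample.int(nl) else {
      idx <- seq_len(nl)
      for (s in levels(strata)) {
        j <- which(strata == s)
        idx[j] <- j[sample.int(length(j))]
      }
      idx
    }
    codes <- geno$codes[, perm, drop = FALSE]
    colnames(codes) <- colnames(geno$codes)  # labels stay, contents move
    out[[i]] <- genotype_matrix(codes, geno$info)
  }
  out
}

#' Permutation-based FDR threshold
#'
#' Finds the p-value threshold `z` such that the estimated false discovery
#' rate \eqn{\hat P(p_0 < z) / \hat P(p_1 < z)} is at most the target `x`,
#' where \eqn{\hat P(p_0 < z)} is the fraction of the pooled permutation-null
#' p-values below `z` (the pool holds `k` null p-values per observed test,
#' so the denominator is `k * length(p1)`) and \eqn{\hat P(p_1 < z)} is the
#' corresponding fraction of the observed p-values.  Candidate thresholds are
#' the distinct observed p-values; inequalities are strict on both sides, and
#' `z` is the largest candidate satisfying the bound with
#' \eqn{\hat P(p_1 < z) > 0}.  Discoveries are the observed tests with
#' `p1 < z`.  When no candidate qualifies, `z` is `NA` and there are no
#' discoveries.
#'
#' @param p1 observed p-values.
#' @param p0_pool pooled permutation-null p-values.
#' @param k permutations per test (4 for the mixed-model scans, 10 for the
#'   fixed-effects splicing refinement).
#' @param x target FDR in (0, 1].
#' @return list: `z`, `n_discoveries`, `discoveries` (logical over `p1`),
#'   `fdr_at_z`, `n_null_below`, `k`, `x`.
#' @export
estimate_fdr_threshold <- function(p1, p0_pool, k, x) {
  stopifnot(length(p1) > 0, x > 0, x <= 1, k >= 1)
  p1 <- as.numeric(p1); p0 <- as.numeric(p0_pool)
  if (anyNA(p1) || anyNA(p0)) stop("p-values must be non-missing; drop failed fits first")
  denom <- k * length(p1)
  cand <- sort(unique(p1))
  best_z <- NA_real_; best_fdr <- NA_real_
  for (z in rev(cand)) {          # largest qualifying candidate wins
    n1 <- sum(p1 < z)
    if (n1 == 0) next
    fdr <- (sum(p0 < z) / denom) / (n1 / length(p1))
    if (fdr <= x) { best_z <- z; best_fdr <- fdr; break }
  }
  disc <- if (is.na(best_z)) rep(FALSE, length(p1)) else p1 < best_z
  list(z = best_z, n_discoveries = sum(disc), discoveries = disc,
       fdr_at_z = best_fdr,
       n_null_below = if (is.na(best_z)) 0L else sum(p0 < best_z),
       k = k, x = x)
}
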