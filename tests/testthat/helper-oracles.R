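# Independent oracles and small fixture builders used across the suite.
# Oracles are deliberately written from first principles (normal equations,
# dense GLS solves, exhaustive scans) and never call the package's fitting
# path.

# closed-form weighted least squares via the normal equations
oracle_wls <- function(X, y, w) {
  A <- t(X) %*% (w * X)
  beta <- solve(A, t(X) %*% (w * y))
  r <- y - X %*% beta
  list(beta = drop(beta), rss = sum(w * r^2),
       se = sqrt(diag(solve(A)) * sum(w * r^2) / (length(y) - ncol(X))))
}

# dense GLS solution at known variance components
oracle_gls <- function(X, y, w, subj, sigma_b2, sigma_e2) {
  Z <- outer(subj, sort(unique(subj)), "==") * 1
  V <- sigma_b2 * Z %*% t(Z) + sigma_e2 * diag(1 / w)
  Vi <- solve(V)
  A <- t(X) %*% Vi %*% X
  drop(solve(A, t(X) %*% Vi %*% y))
}

# balanced one-way ANOVA variance-component estimators (q subjects x k reps)
oracle_anova_vc <- function(y, subj, k) {
  q <- length(unique(subj))
  m_i <- tapply(y, subj, mean)
  mse <- sum((y - m_i[as.character(subj)])^2) / (q * (k - 1))
  msa <- k * sum((m_i - mean(y))^2) / (q - 1)
  list(sigma_e2 = mse, sigma_b2 = max(0, (msa - mse) / k))
}

# exhaustive permutation-FDR threshold scan (mirrors the published rule,
# evaluated at every distinct observed p-value)
oracle_fdr_threshold <- function(p1, p0, k, x) {
  best <- NA_real_
  for (z in sort(unique(p1))) {
    n1 <- sum(p1 < z)
    if (n1 == 0) next
    fdr <- (sum(p0 < z) / (k * length(p1))) / (n1 / length(p1))
    if (fdr <= x) best <- z
  }
  list(z = best, n_discoveries = if (is.na(best)) 0L else sum(p1 < best))
}

# one replicated, grouped, heteroscedastic expression trait generated
# directly from the model equation (no count pathway)
sim_trait <- function(seed, n_lines = 100, beta = 0, sigma_b = 1,
                      sd_groups = c(A = 1, B = 2), maf = 0.3,
                      rep_frac = 0.5) {
  set.seed(seed)
  code_line <- rbinom(n_lines, 2, 1 - maf)
  b <- rnorm(n_lines, 0, sigma_b)
  n_rep <- floor(n_lines * rep_frac)
  subj <- c(seq_len(n_lines), seq_len(n_rep))
  grp <- c(rep("A", n_lines), rep("B", n_rep))
  n <- length(subj)
  y <- c(A = 0, B = 2)[grp] + beta * code_line[subj] + b[subj] +
    rnorm(n, 0, sd_groups[grp])
  data.frame(y = y, group = factor(grp), subject = factor(subj),
             geno = code_line[subj])
}

fit_model1a <- function(d) {
  d$.w <- compute_weights(d$y, d$group)$weight
  suppressWarnings(wlmm(y ~ 0 + group + geno, d, subject = "subject",
                        weights = ".w"))
}

# a 100-cell-line version of the default four-group study design
cfg_100_lines <- function(...) {
  sim_config(n_cell_lines_per_population = c(pop1 = 51, pop2 = 49), ...)
}

# small hand-checkable gene model (plus strand unless told otherwise)
toy_gene <- function(strand = "+", coding = TRUE) {
  data.frame(gene_id = "TG1", chrom = "chr1", strand = strand,
             tx_start = 100000, tx_end = 110000,
             cds_start = 100200, cds_end = 109800,
             exon_starts = "100000,104000,108000",
             exon_ends = "101000,105000,110000",
             n_exons = 3, coding = coding, stringsAsFactors = FALSE)
}

toy_geno <- function(codes, pos = NULL, chrom = "chr1") {
  codes <- as.matrix(codes)
  if (is.null(pos)) pos <- seq_len(nrow(codes)) * 1000L
  if (is.null(rownames(codes)))
    rownames(codes) <- paste0("s", seq_len(nrow(codes)))
  if (is.null(colnames(codes)))
    colnames(codes) <- paste0("L", seq_len(ncol(codes)))
  genotype_matrix(codes, data.frame(snp_id = rownames(codes),
                                    chrom = chrom, pos = pos,
                                    ref = "A", alt = "G",
                                    stringsAsFactors = FALSE))
}
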