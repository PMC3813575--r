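#' cis SNP::gene pairs under the 20 kb flank rule
#'
#' A SNP is cis to a gene when its position lies in
#' `[tx_start - flank, tx_end + flank]` (1-based inclusive on both
#' boundaries) on the gene's chromosome; the gene span is taken genomically
#' (min/max of transcript coordinates, strand-agnostic) since the flanks are
#' symmetric.
#'
#' @param geno a [genotype_matrix()].
#' @param gene_models gene-model data frame (see [simulate_gene_models()]).
#' @param flank flank size in nt (default 20000).
#' @return list: `cis_sets` (gene id -> cis SNP ids, genes with none
#'   included as empty), `pairs` (data frame `snp_id`, `gene_id`,
#'   `distance`; distance 0 inside the gene span).
#' @export
find_cis_pairs <- function(geno, gene_models, flank = 20000) {
  stopifnot(inherits(geno, "geno_matrix"))
  info <- geno$info
  unknown <- setdiff(unique(info$chrom), unique(gene_models$chrom))
  if (length(unknown))
    stop("SNP chromosome(s) not present in the gene models: ",
         paste(unknown, collapse = ", "))
  cis_sets <- list(); rows <- list()
  for (i in seq_len(nrow(gene_models))) {
    g <- gene_models[i, ]
    hit <- info$chrom == g$chrom & info$pos >= g$tx_start - flank &
      info$pos <= g$tx_end + flank
    cis_sets[[g$gene_id]] <- info$snp_id[hit]
    if (any(hit)) {
      pos <- info$pos[hit]
      d <- pmax(0L, pmax(g$tx_start - pos, pos - g$tx_end))
      rows[[length(rows) + 1]] <- data.frame(
        snp_id = info$snp_id[hit], gene_id = g$gene_id, distance = d,
        stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(snp_id = character(0), gene_id = character(0),
               distance = integer(0))
  list(cis_sets = cis_sets, pairs = pairs)
}

#' Classify a SNP::gene pair as cis, trans or neither
#'
#' cis: within the flanked gene span.  trans: different chromosome, or same
#' chromosome with at least `trans_dist` nt between the SNP and the nearer
#' gene boundary.  Pairs in the band between `flank` and `trans_dist` are
#' neither and are never tested.
#'
#' @param snp_chrom,snp_pos SNP coordinates (vectors recycle against the
#'   gene arguments).
#' @param gene_chrom,gene_start,gene_end gene span.
#' @param flank,trans_dist rule parameters (nt).
#' @return character vector in `{"cis", "trans", "neither"}`.
#' @export
pair_relation <- function(snp_chrom, snp_pos, gene_chrom, gene_start,
                          gene_end, flank = 20000, trans_dist = 1e6) {
  n <- max(length(snp_pos), length(gene_start))
  snp_chrom <- rep_len(snp_chrom, n); snp_pos <- rep_len(snp_pos, n)
  gene_chrom <- rep_len(gene_chrom, n)
  gene_start <- rep_len(gene_start, n); gene_end <- rep_len(gene_end, n)
  d <- pmax(0, pmax(gene_start - snp_pos, snp_pos - gene_end))
  out <- ifelse(snp_chrom != gene_chrom, "trans",
                ifelse(d <= flank, "cis",
                       ifelse(d >= trans_dist, "trans", "neither")))
  out
}

# ---- internal fitting plumbing ---------------------------------------------

.occupancy_ok <- function(code, min_n = 3L, min_classes = 2L) {
  tab <- table(code)
  sum(tab >= min_n) >= min_classes && length(tab) >= 2
}

.fit_formula <- function(splicing) {
  if (splicing) y ~ 0 + group:exon + geno:exon else y ~ 0 + group + geno
}

# one association p-value for an assembled design; returns list(p, note)
.fit_pair <- function(d, engine, splicing) {
  f <- .fit_formula(splicing)
  fit <- tryCatch(suppressWarnings(switch(engine,
    wlmm = wlmm(f, d, subject = "subject", weights = ".w"),
    hlm  = wlmm(f, d, weights = ".w"),
    olm  = wlmm(f, d))), error = function(e) NULL)
  if (is.null(fit)) return(list(p = NA_real_, note = "fit_error"))
  tst <- if (splicing) test_interaction(fit) else test_genotype_effect(fit)
  list(p = tst$p, note = tst$note)
}

# per-gene cached expression design (everything but the genotype column)
.expr_design <- function(gene, expr, samples) {
  y <- expr[gene, samples$sample_id]
  w <- compute_weights(y, samples$group)$weight
  data.frame(y = as.numeric(y), group = factor(samples$group),
             subject = factor(samples$cell_line), .w = w,
             cell_line = samples$cell_line, stringsAsFactors = FALSE)
}

# per-gene cached splicing design in long form; NULL when unusable
.splice_design <- function(gene, index, samples) {
  idx <- index[[gene]]
  if (is.null(idx) || nrow(idx) < 2) return(NULL)
  ok_samp <- !is.na(idx[1, ])
  idx <- idx[, ok_samp, drop = FALSE]
  sm <- samples[match(colnames(idx), samples$sample_id), ]
  ne <- nrow(idx); ns <- ncol(idx)
  d <- data.frame(y = as.vector(idx),
                  exon = factor(rep(rownames(idx), ns)),
                  group = factor(rep(sm$group, each = ne)),
                  subject = factor(rep(sm$cell_line, each = ne)),
                  cell_line = rep(sm$cell_line, each = ne),
                  sample_id = rep(sm$sample_id, each = ne),
                  stringsAsFactors = FALSE)
  d$.w <- compute_weights(d$y, d$group, d$exon, mode = "per_group_exon")$weight
  d
}

# run one mechanism's tests for a pair list against a given code matrix
.scan_pairs <- function(pairs, codes, designs, engine, splicing,
                        min_n = 3L, min_classes = 2L) {
  res <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    snp <- pairs$snp_id[i]; gene <- pairs$gene_id[i]
    d <- designs[[gene]]
    if (is.null(d)) { res[[i]] <- c(NA, "single_exon"); next }
    code <- codes[snp, d$cell_line]
    keep <- !is.na(code)
    if (splicing) {
      per_samp <- code[!duplicated(d$sample_id)]
      occ <- .occupancy_ok(per_samp[!is.na(per_samp)], min_n, min_classes)
    } else {
      occ <- .occupancy_ok(code[keep], min_n, min_classes)
    }
    if (!occ) { res[[i]] <- c(NA, "occupancy"); next }
    dd <- d[keep, , drop = FALSE]
    dd$geno <- as.numeric(code[keep])
    dd$group <- droplevels(dd$group)
    dd$subject <- droplevels(dd$subject)
    if (splicing) dd$exon <- droplevels(dd$exon)
    ft <- .fit_pair(dd, engine, splicing)
    res[[i]] <- c(ft$p, if (nzchar(ft$note)) ft$note else "ok")
  }
  data.frame(snp_id = pairs$snp_id, gene_id = pairs$gene_id,
             p = as.numeric(vapply(res, `[`, "", 1)),
             note = vapply(res, `[`, "", 2), stringsAsFactors = FALSE)
}

# observed + permuted p-values and the FDR threshold for one scan stage
.scan_stage <- function(pairs, geno, designs, engine, splicing, k, x, seed,
                        strata = NULL) {
  obs <- .scan_pairs(pairs, geno$codes, designs, engine, splicing)
  testable <- !is.na(obs$p)
  p1 <- obs$p[testable]
  if (length(p1) == 0)
    return(list(tests = obs, threshold = NA_real_, fdr = NULL,
                calls = obs[0, ], n_perm_failed = 0L))
  perms <- permute_genotypes(geno, k, seed, strata = strata)
  p0 <- unlist(lapply(perms, function(pg)
    .scan_pairs(pairs[testable, , drop = FALSE], pg$codes, designs, engine,
                splicing)$p))
  n_perm_failed <- sum(is.na(p0))
  p0 <- p0[!is.na(p0)]
  est <- estimate_fdr_threshold(p1, p0, k, x)
  calls <- obs[testable, ][est$discoveries, , drop = FALSE]
  list(tests = obs, threshold = est$z, fdr = est, calls = calls,
       n_perm_failed = n_perm_failed)
}

# ---- user-facing scans ------------------------------------------------------

#' cis eQTL scan
#'
#' Fits the expression model (`y ~ 0 + group + geno` with a random cell-line
#' intercept and per-group inverse-variance weights when
#' `engine = "wlmm"`) for every cis SNP::gene pair, builds the permutation
#' null by re-running the scan on `k` cell-line-permuted genotype matrices,
#' and calls eQTL SNPs at the permutation-FDR threshold for target `x`.
#' The reported p-value threshold is the permutation-derived `z` for this
#' dataset, not a fixed constant.
#'
#' @param geno a [genotype_matrix()].
#' @param expr genes x samples expression matrix.
#' @param samples sample sheet (`sample_id`, `cell_line`, `group`, ...).
#' @param cis_sets gene -> cis SNP ids (typically the `kept` element of
#'   [ld_prune()] or `cis_sets` of [find_cis_pairs()]).
#' @param x target FDR (default 0.01).
#' @param k permutations (default 4).
#' @param seed integer seed for the permutations.
#' @param engine `"wlmm"` (default), `"hlm"` or `"olm"`.
#' @param strata optional per-cell-line strata for stratified permutation.
#' @return list of class `"qtl_scan"`: `calls` (discovered pairs), `tests`
#'   (all pairs with p and note), `threshold` (the raw-p threshold `z`),
#'   `fdr` (full [estimate_fdr_threshold()] result), `excluded` (untestable
#'   pairs with reasons), `class` = "eQTL".
#' @export
scan_eqtl <- function(geno, expr, samples, cis_sets, x = 0.01, k = 4,
                      seed = 1, engine = c("wlmm", "hlm", "olm"),
                      strata = NULL) {
  engine <- match.arg(engine)
  pairs <- .sets_to_pairs(cis_sets)
  genes <- unique(pairs$gene_id)
  designs <- stats::setNames(
    lapply(genes, .expr_design, expr = expr, samples = samples), genes)
  st <- .scan_stage(pairs, geno, designs, engine, splicing = FALSE,
                    k = k, x = x, seed = seed, strata = strata)
  .qtl_scan_result(st, "eQTL")
}

#' Two-step cis sQTL scan
#'
#' Step 1 fits the mixed splicing model (genotype-by-exon interaction on the
#' rescaled exon index, `y ~ 0 + group:exon + geno:exon` with random
#' cell-line intercept and per-group-by-exon weights) for every multi-exon
#' cis pair, and screens at permutation FDR `x1` with `k1` permutations.
#' Step 2 refits the surviving pairs with the fixed-effects (weighted least
#' squares) splicing model and refines at permutation FDR `x2` with `k2`
#' permutations.  Final sQTL calls survive both steps; single-exon genes and
#' mixed-model convergence failures are excluded and counted.
#'
#' @param geno,samples as in [scan_eqtl()].
#' @param index rescaled exon index tensor ([exon_index_tensor()]).
#' @param cis_sets gene -> cis SNP ids.
#' @param x1,k1 step-1 (mixed model) FDR target and permutation count.
#' @param x2,k2 step-2 (fixed-effects model) FDR target and permutation
#'   count.
#' @param seed integer seed.
#' @param strata optional stratified permutation.
#' @return list of class `"qtl_scan"` with `calls`, `step1`, `step2`,
#'   `threshold` (named: step1, step2), `excluded`, `class` = "sQTL".
#' @export
scan_sqtl_two_step <- function(geno, index, samples, cis_sets, x1 = 0.05,
                               k1 = 4, x2 = 0.01, k2 = 10, seed = 1,
                               strata = NULL) {
  pairs <- .sets_to_pairs(cis_sets)
  genes <- unique(pairs$gene_id)
  designs <- stats::setNames(
    lapply(genes, .splice_design, index = index, samples = samples), genes)
  st1 <- .scan_stage(pairs, geno, designs, "wlmm", splicing = TRUE,
                     k = k1, x = x1, seed = seed, strata = strata)
  surv <- st1$calls[, c("snp_id", "gene_id")]
  if (nrow(surv) == 0) {
    out <- list(calls = st1$calls, step1 = st1, step2 = NULL,
                threshold = c(step1 = st1$threshold, step2 = NA_real_),
                excluded = st1$tests[is.na(st1$tests$p), ], class = "sQTL")
    class(out) <- "qtl_scan"
    return(out)
  }
  st2 <- .scan_stage(surv, geno, designs, "hlm", splicing = TRUE,
                     k = k2, x = x2, seed = seed + 1L, strata = strata)
  calls <- st2$calls
  p1 <- st1$tests$p[match(paste(calls$snp_id, calls$gene_id),
                          paste(st1$tests$snp_id, st1$tests$gene_id))]
  if (nrow(calls)) {
    calls$p_model2a <- p1
    names(calls)[names(calls) == "p"] <- "p_model2b"
  }
  out <- list(calls = calls, step1 = st1, step2 = st2,
              threshold = c(step1 = st1$threshold, step2 = st2$threshold),
              excluded = st1$tests[is.na(st1$tests$p), ], class = "sQTL")
  class(out) <- "qtl_scan"
  out
}

#' Trans scan from called cis QTL SNPs
#'
#' Only SNPs already called as cis eQTL or sQTL SNPs are scanned (the
#' mediation assumption: the regulator gene itself must be associated with
#' the SNP).  For each such SNP, every gene trans to it (different
#' chromosome, or at least `trans_dist` nt away on the same chromosome) is
#' tested: trans-expression with the expression model at the cis eQTL scan's
#' raw-p threshold, and trans-splicing either with the full two-step
#' thresholds (`rule = "two_step"`, default) or with the fixed-effects model
#' alone at the step-2 threshold (`rule = "model2b_only"`).
#'
#' @param cis_snps character vector of called cis QTL SNP ids (union of both
#'   classes).
#' @param geno,expr,index,samples,gene_models study inputs.
#' @param thresholds named numeric: `eqtl` (raw-p threshold from
#'   [scan_eqtl()]), `sqtl_step1`, `sqtl_step2` (from
#'   [scan_sqtl_two_step()]); `NA` disables the corresponding mechanism.
#' @param trans_dist minimum same-chromosome distance in nt.
#' @param flank cis flank (pairs between `flank` and `trans_dist` are never
#'   tested).
#' @param rule trans-splicing criterion, see above.
#' @return list: `calls` (data frame `snp_id`, `gene_id`, `mechanism`
#'   ("expression"/"splicing"), `p` columns), `tests` per mechanism.
#' @export
scan_trans <- function(cis_snps, geno, expr, index, samples, gene_models,
                       thresholds, trans_dist = 1e6, flank = 20000,
                       rule = c("two_step", "model2b_only")) {
  rule <- match.arg(rule)
  stopifnot(all(cis_snps %in% geno$info$snp_id))
  info <- geno$info[match(cis_snps, geno$info$snp_id), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(info))) {
    rel <- pair_relation(info$chrom[i], info$pos[i], gene_models$chrom,
                         gene_models$tx_start, gene_models$tx_end,
                         flank = flank, trans_dist = trans_dist)
    tg <- gene_models$gene_id[rel == "trans"]
    if (length(tg))
      rows[[length(rows) + 1]] <- data.frame(snp_id = info$snp_id[i],
                                             gene_id = tg,
                                             stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(list(calls = .empty_trans_calls(), tests = NULL))
  pairs <- do.call(rbind, rows)
  genes <- unique(pairs$gene_id)

  calls <- list(); tests <- list()
  if (is.finite(thresholds[["eqtl"]])) {
    de <- stats::setNames(lapply(genes, .expr_design, expr = expr,
                                 samples = samples), genes)
    te <- .scan_pairs(pairs, geno$codes, de, "wlmm", splicing = FALSE)
    tests$expression <- te
    hit <- !is.na(te$p) & te$p < thresholds[["eqtl"]]
    if (any(hit))
      calls$expression <- data.frame(te[hit, c("snp_id", "gene_id")],
                                     mechanism = "expression",
                                     p = te$p[hit], stringsAsFactors = FALSE)
  }
  z2 <- thresholds[["sqtl_step2"]]
  if (is.finite(z2)) {
    ds <- stats::setNames(lapply(genes, .splice_design, index = index,
                                 samples = samples), genes)
    tb <- .scan_pairs(pairs, geno$codes, ds, "hlm", splicing = TRUE)
    hit2 <- !is.na(tb$p) & tb$p < z2
    if (rule == "two_step") {
      z1 <- thresholds[["sqtl_step1"]]
      ta <- .scan_pairs(pairs, geno$codes, ds, "wlmm", splicing = TRUE)
      hit1 <- !is.na(ta$p) & is.finite(z1) & ta$p < z1
      hit <- hit1 & hit2
      tests$splicing <- data.frame(tb[, c("snp_id", "gene_id")],
                                   p_model2a = ta$p, p_model2b = tb$p,
                                   stringsAsFactors = FALSE)
    } else {
      hit <- hit2
      tests$splicing <- data.frame(tb[, c("snp_id", "gene_id")],
                                   p_model2a = NA_real_, p_model2b = tb$p,
                                   stringsAsFactors = FALSE)
    }
    if (any(hit))
      calls$splicing <- data.frame(tb[hit, c("snp_id", "gene_id")],
                                   mechanism = "splicing",
                                   p = tb$p[hit], stringsAsFactors = FALSE)
  }
  calls <- if (length(calls)) do.call(rbind, calls) else .empty_trans_calls()
  rownames(calls) <- NULL
  list(calls = calls, tests = tests)
}

.empty_trans_calls <- function()
  data.frame(snp_id = character(0), gene_id = character(0),
             mechanism = character(0), p = numeric(0))

#' Tag-SNP selection
#'
#' Flags, per gene (and per QTL class if present), the gene-wide most
#' significant SNP.  Exact p-value ties are broken by smallest genomic
#' position and flagged.
#'
#' @param calls data frame with columns `snp_id`, `gene_id`, a p-value
#'   column, and optionally `class`.
#' @param geno a [genotype_matrix()] (for positions).
#' @param p_col name of the p-value column (default `"p"`).
#' @return `calls` with added logical columns `tag` and `tag_tie`.
#' @export
select_tag_snps <- function(calls, geno, p_col = "p") {
  stopifnot(p_col %in% names(calls))
  calls$tag <- FALSE; calls$tag_tie <- FALSE
  if (nrow(calls) == 0) return(calls)
  pos <- geno$info$pos[match(calls$snp_id, geno$info$snp_id)]
  key <- if ("class" %in% names(calls))
    paste(calls$gene_id, calls$class) else calls$gene_id
  for (k in unique(key)) {
    i <- which(key == k)
    pmin_ <- min(calls[[p_col]][i])
    best <- i[calls[[p_col]][i] == pmin_]
    tie <- length(best) > 1
    pick <- best[which.min(pos[best])]
    calls$tag[pick] <- TRUE
    calls$tag_tie[pick] <- tie
  }
  calls
}

#' Overlap of two QTL SNP id sets
#'
#' Plain set arithmetic: intersection size and its percentage of each set,
#' rounded to one decimal as conventionally printed.
#' @param eqtl_snps,sqtl_snps character vectors of SNP ids (or set sizes can
#'   be recovered from any vectors; duplicates are removed).
#' @export
qtl_overlap_stats <- function(eqtl_snps, sqtl_snps) {
  e <- unique(eqtl_snps); s <- unique(sqtl_snps)
  ov <- length(intersect(e, s))
  list(n_eqtl = length(e), n_sqtl = length(s), n_overlap = ov,
       pct_of_eqtl = round(100 * ov / length(e), 1),
       pct_of_sqtl = round(100 * ov / length(s), 1))
}

.sets_to_pairs <- function(cis_sets) {
  rows <- lapply(names(cis_sets), function(g)
    if (length(cis_sets[[g]]))
      data.frame(snp_id = cis_sets[[g]], gene_id = g,
                 stringsAsFactors = FALSE))
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(snp_id = character(0), gene_id = character(0)))
  do.call(rbind, rows)
}

.qtl_scan_result <- function(stage, class) {
  out <- list(calls = stage$calls, tests = stage$tests,
              threshold = stage$threshold, fdr = stage$fdr,
              excluded = stage$tests[is.na(stage$tests$p), ],
              n_perm_failed = stage$n_perm_failed, class = class)
  class(out) <- "qtl_scan"
  out
}

#' @export
print.qtl_scan <- function(x, ...) {
  cat(x$class, "scan:", nrow(x$calls), "calls from",
      sum(!is.na(x$tests$p)), "testable pairs")
  if (length(x$threshold) == 1)
    cat("; raw-p threshold z =", format(x$threshold, digits = 3))
  cat("\n")
  invisible(x)
}
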