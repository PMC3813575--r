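#' Configuration for the synthetic QTL study generator
#'
#' Builds and validates the parameter set from which [simulate_genotypes()]
#' and [simulate_expression()] generate a complete synthetic study: genotypes
#' with Hardy-Weinberg class frequencies and block LD, a grouped and
#' replicated sample design over two populations, gene-level expression with
#' group batch offsets, group-specific residual variances and a per-cell-line
#' random effect, and exon-level counts whose rescaled indexes carry planted
#' genotype-by-exon (splicing) interactions.
#'
#' The default design mirrors a four-group, two-population study: group A
#' (41 lines, pop1) and group C (59 lines, pop1) overlap in 29 lines, and
#' groups B1/B2 measure the same 69 pop2 lines once each, so 70% of the 140
#' cell lines are measured twice.  Group residual standard deviations differ
#' (deepest dataset least noisy), giving the heteroscedasticity the weighted
#' models exist for.
#'
#' @param n_cell_lines_per_population named integer vector, lines per
#'   population.
#' @param group_layout data frame with columns `group`, `population`, `frac`
#'   (fraction of the population's lines measured in this group),
#'   `replicates` (>= 1 samples per included line), `anchor` ("start"/"end":
#'   which end of the population's line list the group draws from, which
#'   controls between-group line overlap).
#' @param n_snps,n_genes totals; SNPs are placed round-robin in the cis
#'   windows of the genes.
#' @param maf_range minor-allele-frequency range, within (0, 0.5].
#' @param ld_block_size,ld_rho consecutive SNPs of a gene form blocks of this
#'   size whose latent allele dosages follow an AR(1) Gaussian copula with
#'   correlation `ld_rho` in [0, 1).
#' @param missing_rate per-call missingness probability.
#' @param exons_per_gene_range inclusive range of exon counts per gene.
#' @param n_eqtl_genes,n_sqtl_genes how many genes carry a planted cis eQTL /
#'   sQTL (disjoint sets, assigned from the start of the gene list).
#' @param beta_G_eqtl additive genotype effect on expression, units per
#'   reference-allele copy.
#' @param gamma_interaction_sqtl genotype-by-exon effect on the rescaled exon
#'   index, index units per allele copy (applied with a +/-0.5 two-exon
#'   contrast).
#' @param signal_strength_ladder per-class effect multipliers: the k-th
#'   planted gene of a class gets `ladder[min(k, length(ladder))]` times the
#'   class effect size.  Real QTLs come in a spectrum of strengths, and the
#'   borderline signals are what give the permutation-FDR threshold its
#'   resolution near the cutoff; the default plants four full-strength genes
#'   (the trans hubs) plus a 0.6x and a 0.4x gene per class.
#' @param group_offsets,group_residual_sd named per-group batch offsets and
#'   residual standard deviations (expression units).
#' @param sigma_b cell-line random-effect standard deviation.
#' @param baseline_expr mean expression level of a gene (FPKM-like units).
#' @param exon_length_range exon lengths in nt.
#' @param lib_size_by_group named mean library sizes (mapped reads/sample).
#' @param trans_arch `"default"` or a list of entries
#'   `list(snp=, targets=, effect=, mechanism=)` with
#'   `mechanism` in `{"expression", "splicing"}`; the SNP must be a planted
#'   cis e/sQTL SNP and targets must be genes trans to it.  The default
#'   architecture plants one hub per paradigm C1-C4.
#' @param seed integer; fully determines all generated output.
#' @return validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_cell_lines_per_population = c(pop1 = 71, pop2 = 69),
                       group_layout = default_group_layout(),
                       n_snps = 240, maf_range = c(0.1, 0.5),
                       ld_block_size = 4, ld_rho = 0.8, missing_rate = 0.01,
                       n_genes = 30, exons_per_gene_range = c(4, 8),
                       n_eqtl_genes = 6, n_sqtl_genes = 6,
                       beta_G_eqtl = 1.5, gamma_interaction_sqtl = 1.0,
                       signal_strength_ladder = c(1, 1, 1, 1, 0.6, 0.4),
                       group_offsets = c(A = 0, B1 = 2, B2 = 1.5, C = -1),
                       group_residual_sd = c(A = 1, B1 = 2, B2 = 2, C = 1.2),
                       sigma_b = 1, baseline_expr = 10,
                       exon_length_range = c(150, 500),
                       lib_size_by_group = c(A = 4e7, B1 = 8e6, B2 = 8e6,
                                             C = 2e7),
                       trans_arch = "default", seed = 1) {
  cfg <- as.list(environment())
  if (any(maf_range <= 0) || any(maf_range > 0.5) || maf_range[1] > maf_range[2])
    stop("maf_range must lie in (0, 0.5]")
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must be in [0, 1)")
  if (any(group_residual_sd <= 0)) stop("group residual sds must be > 0")
  if (sigma_b < 0) stop("sigma_b must be >= 0")
  if (any(group_layout$replicates < 1)) stop("replicates per line must be >= 1")
  if (!all(group_layout$group %in% names(group_offsets)) ||
      !all(group_layout$group %in% names(group_residual_sd)) ||
      !all(group_layout$group %in% names(lib_size_by_group)))
    stop("group_offsets / group_residual_sd / lib_size_by_group must name every group")
  if (!all(group_layout$population %in% names(n_cell_lines_per_population)))
    stop("unknown population in group_layout")
  if (n_eqtl_genes + n_sqtl_genes > n_genes)
    stop("more signal genes than genes")
  if (seed < 0 || seed > 2^31 - 100) stop("seed must be a small non-negative integer")
  class(cfg) <- "sim_config"
  cfg
}

#' @rdname sim_config
#' @export
default_group_layout <- function() {
  data.frame(group = c("A", "B1", "B2", "C"),
             population = c("pop1", "pop2", "pop2", "pop1"),
             frac = c(41 / 71, 1, 1, 59 / 71),
             replicates = 1L,
             anchor = c("start", "start", "start", "end"),
             stringsAsFactors = FALSE)
}

#' Deterministic synthetic gene models
#'
#' Lays out `n_genes` protein-coding gene models on two chromosomes, 2 Mb
#' apart (so genes other than a SNP's host are always trans under the 1 Mb
#' rule), with alternating strand, 2 kb introns and 100 nt terminal UTR
#' stubs.  Coordinates are 1-based inclusive.
#'
#' @param cfg a [sim_config()].
#' @return data frame: `gene_id`, `chrom`, `strand`, `tx_start`, `tx_end`,
#'   `cds_start`, `cds_end`, `exon_starts`, `exon_ends` (comma strings),
#'   `n_exons`, `coding`.
#' @export
simulate_gene_models <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr_seed <- .local_seed(cfg$seed + 11L)
  on.exit(withr_seed())
  n <- cfg$n_genes
  er <- cfg$exons_per_gene_range
  out <- vector("list", n)
  sample_range <- function(lo, hi, k)   # safe for lo == hi
    if (lo == hi) rep(lo, k) else sample(seq(lo, hi), k, replace = TRUE)
  for (i in seq_len(n)) {
    ne <- sample_range(er[1], er[2], 1)
    lens <- sample_range(cfg$exon_length_range[1], cfg$exon_length_range[2], ne)
    chrom <- paste0("chr", (i - 1) %% 2 + 1)
    tx_start <- 1e6 + ((i - 1) %/% 2) * 2e6
    starts <- integer(ne); ends <- integer(ne)
    pos <- tx_start
    for (e in seq_len(ne)) {
      starts[e] <- pos; ends[e] <- pos + lens[e] - 1
      pos <- ends[e] + 2001L  # 2 kb introns
    }
    tx_end <- ends[ne]
    utr <- pmin(100L, lens - 1L)
    out[[i]] <- data.frame(
      gene_id = sprintf("G%02d", i), chrom = chrom,
      strand = c("+", "-")[(i - 1) %% 2 + 1],
      tx_start = tx_start, tx_end = tx_end,
      cds_start = starts[1] + utr[1], cds_end = ends[ne] - utr[ne],
      exon_starts = paste(starts, collapse = ","),
      exon_ends = paste(ends, collapse = ","),
      n_exons = ne, coding = TRUE, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# save/restore the RNG state around a locally seeded block
.local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}

.sim_line_ids <- function(cfg) {
  unlist(lapply(names(cfg$n_cell_lines_per_population), function(p)
    sprintf("%s_L%03d", p, seq_len(cfg$n_cell_lines_per_population[[p]]))),
    use.names = FALSE)
}

# round-robin placement of SNPs into the genes' cis windows; ids encode the
# host gene so planted-truth bookkeeping stays readable
.sim_snp_placement <- function(cfg, gm) {
  n_per <- rep(cfg$n_snps %/% cfg$n_genes, cfg$n_genes)
  extra <- cfg$n_snps %% cfg$n_genes
  if (extra > 0) n_per[seq_len(extra)] <- n_per[seq_len(extra)] + 1
  out <- vector("list", cfg$n_genes)
  for (i in seq_len(cfg$n_genes)) {
    if (n_per[i] == 0) next
    lo <- gm$tx_start[i] - 20000L; hi <- gm$tx_end[i] + 20000L
    pos <- sort(sample(seq(lo, hi), n_per[i]))
    out[[i]] <- data.frame(
      snp_id = sprintf("%s_s%02d", gm$gene_id[i], seq_len(n_per[i])),
      chrom = gm$chrom[i], pos = pos, ref = "A", alt = "G",
      host_gene = gm$gene_id[i], stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate Hardy-Weinberg genotypes with block LD
#'
#' Each SNP's minor-allele frequency is drawn uniformly from
#' `cfg$maf_range` and its reference allele is the major allele, so genotype
#' codes count reference alleles under Hardy-Weinberg equilibrium.  Within a
#' gene, consecutive SNPs form LD blocks of `ld_block_size`: the two latent
#' haplotype dosages of each line follow an AR(1) Gaussian copula with
#' lag-one correlation `ld_rho`, giving tunable pairwise genotype-code
#' correlation inside a block and independence across blocks.  A fraction
#' `missing_rate` of calls is masked to `NA`; the complete pre-masking codes
#' are kept in the attribute `"complete"` for downstream signal planting.
#'
#' @param cfg a [sim_config()].
#' @return a [genotype_matrix()] (with `$info$host_gene` recording the gene
#'   whose cis window each SNP was placed in).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  gm <- simulate_gene_models(cfg)
  restore <- .local_seed(cfg$seed + 23L)
  on.exit(restore())
  info <- .sim_snp_placement(cfg, gm)
  lines <- .sim_line_ids(cfg)
  n_lines <- length(lines)
  n_snps <- nrow(info)
  maf <- stats::runif(n_snps, cfg$maf_range[1], cfg$maf_range[2])
  p_ref <- 1 - maf
  codes <- matrix(0L, n_snps, n_lines, dimnames = list(info$snp_id, lines))
  rho <- cfg$ld_rho
  by_gene <- split(seq_len(n_snps), info$host_gene)
  for (snps in by_gene) {
    blocks <- split(snps, ceiling(seq_along(snps) / cfg$ld_block_size))
    for (blk in blocks) {
      B <- length(blk)
      for (hap in 1:2) {
        z <- matrix(stats::rnorm(n_lines * B), n_lines, B)
        if (B > 1 && rho > 0)
          for (j in 2:B) z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
        thr <- stats::qnorm(p_ref[blk])
        is_ref <- sweep(z, 2, thr, "<")
        codes[blk, ] <- codes[blk, ] + t(is_ref)
      }
    }
  }
  complete <- codes
  if (cfg$missing_rate > 0) {
    mask <- matrix(stats::runif(length(codes)) < cfg$missing_rate,
                   nrow(codes), ncol(codes))
    codes[mask] <- NA_integer_
  }
  g <- genotype_matrix(codes, info)
  attr(g, "complete") <- complete
  attr(g, "maf") <- stats::setNames(maf, info$snp_id)
  g
}

.resolve_trans_arch <- function(cfg, gm, info) {
  eqtl_genes <- gm$gene_id[seq_len(cfg$n_eqtl_genes)]
  sqtl_genes <- gm$gene_id[cfg$n_eqtl_genes + seq_len(cfg$n_sqtl_genes)]
  null_genes <- setdiff(gm$gene_id, c(eqtl_genes, sqtl_genes))
  causal <- function(g) info$snp_id[info$host_gene == g][1]
  arch <- cfg$trans_arch
  if (identical(arch, "default")) {
    pick <- function(k, off) null_genes[seq_len(k) + off]
    arch <- list()
    if (length(eqtl_genes) >= 4 && length(sqtl_genes) >= 4 &&
        length(null_genes) >= 16) {
      # two hubs per paradigm with two targets each: the module landscape is
      # many small stars, and no single regulator carries a large share of
      # the planted edges
      hub <- function(g, off, mech)
        list(snp = causal(g), targets = pick(2, off),
             effect = if (mech == "expression") 2.0 else 0.8,
             mechanism = mech)
      arch <- list(
        hub(eqtl_genes[1], 0, "expression"),   # C1
        hub(eqtl_genes[3], 2, "expression"),   # C1
        hub(eqtl_genes[2], 4, "splicing"),     # C3
        hub(eqtl_genes[4], 6, "splicing"),     # C3
        hub(sqtl_genes[1], 8, "expression"),   # C2
        hub(sqtl_genes[3], 10, "expression"),  # C2
        hub(sqtl_genes[2], 12, "splicing"),    # C4
        hub(sqtl_genes[4], 14, "splicing"))    # C4
    } else if (length(eqtl_genes) >= 2 && length(sqtl_genes) >= 2 &&
               length(null_genes) >= 10) {
      arch <- list(
        list(snp = causal(eqtl_genes[1]), targets = pick(3, 0),
             effect = 2.0, mechanism = "expression"),              # C1
        list(snp = causal(eqtl_genes[2]), targets = pick(2, 3),
             effect = 0.8, mechanism = "splicing"),                # C3
        list(snp = causal(sqtl_genes[1]), targets = pick(3, 5),
             effect = 2.0, mechanism = "expression"),              # C2
        list(snp = causal(sqtl_genes[2]), targets = pick(2, 8),
             effect = 0.8, mechanism = "splicing"))                # C4
    }
  }
  if (identical(arch, "none") || is.null(arch)) arch <- list()
  for (a in arch) {
    if (!a$snp %in% info$snp_id) stop("trans_arch: unknown SNP ", a$snp)
    if (!all(a$targets %in% gm$gene_id))
      stop("trans_arch: unknown target gene(s) ",
           paste(setdiff(a$targets, gm$gene_id), collapse = ", "))
    if (!a$mechanism %in% c("expression", "splicing"))
      stop("trans_arch: mechanism must be 'expression' or 'splicing'")
    host <- info$host_gene[match(a$snp, info$snp_id)]
    if (host %in% a$targets)
      stop("trans_arch: target equals the SNP's host gene")
  }
  list(arch = arch, eqtl_genes = eqtl_genes, sqtl_genes = sqtl_genes,
       null_genes = null_genes)
}

#' Simulate the sample sheet, expression matrix and exon count tensor
#'
#' Generates, for every sample `i` of cell line `l` in group `g`:
#' \deqn{y_{gi} = \mu_g + \delta_{grp(i)} + \beta_G \cdot code_{l} + b_l +
#' \epsilon_i,\quad b_l \sim N(0,\sigma_b^2),\ \epsilon_i \sim
#' N(0, sd_{grp(i)}^2)} with the genotype term present for planted eQTL genes
#' and trans-expression targets.  Exon read counts are Poisson draws around
#' the RPKM-implied mean for a target rescaled index
#' `a_e + d_{grp,e} + gamma * code * c_e` (exon profile, group-by-exon batch
#' deviation, and the planted genotype-by-exon contrast for sQTL genes and
#' trans-splicing targets), so the index pathway carries exactly the effects
#' the splicing models test.  All samples of one cell line share its genotype
#' codes and its subject effect.
#'
#' @param cfg a [sim_config()].
#' @param genotypes output of [simulate_genotypes()] for the same `cfg`.
#' @return list of class `"sim_study"`: `samples` (sample sheet), `expr`
#'   (genes x samples), `exons` (list: `counts` gene -> exons x samples
#'   matrix, `lengths` gene -> nt vector, `lib_sizes` per sample), `truth`
#'   (`eqtl_pairs`, `sqtl_pairs`, `trans_edges`, `variance_components`,
#'   `null_genes`), `gene_models`, `genotypes`, `config`.
#' @export
simulate_expression <- function(cfg, genotypes) {
  stopifnot(inherits(cfg, "sim_config"), inherits(genotypes, "geno_matrix"))
  gm <- simulate_gene_models(cfg)
  info <- genotypes$info
  lines_all <- .sim_line_ids(cfg)
  if (!all(lines_all %in% colnames(genotypes$codes)))
    stop("genotypes do not cover all simulated cell lines")
  arch <- .resolve_trans_arch(cfg, gm, info)
  restore <- .local_seed(cfg$seed + 37L)
  on.exit(restore())

  # ---- sample sheet -------------------------------------------------------
  rows <- list()
  for (k in seq_len(nrow(cfg$group_layout))) {
    gl <- cfg$group_layout[k, ]
    pop_lines <- grep(paste0("^", gl$population, "_"), lines_all, value = TRUE)
    n_take <- max(1L, min(length(pop_lines), ceiling(gl$frac * length(pop_lines))))
    take <- if (gl$anchor == "end") utils::tail(pop_lines, n_take)
            else utils::head(pop_lines, n_take)
    for (r in seq_len(gl$replicates))
      rows[[length(rows) + 1]] <- data.frame(
        cell_line = take, group = gl$group, population = gl$population,
        stringsAsFactors = FALSE)
  }
  samples <- do.call(rbind, rows)
  samples$sample_id <- sprintf("S%03d", seq_len(nrow(samples)))
  samples <- samples[, c("sample_id", "cell_line", "group", "population")]
  ns <- nrow(samples)

  # ---- per-line subject effects and complete genotype codes ---------------
  b <- stats::rnorm(length(lines_all), 0, cfg$sigma_b)
  names(b) <- lines_all
  complete <- attr(genotypes, "complete")
  if (is.null(complete)) {
    complete <- genotypes$codes
    complete[is.na(complete)] <- 0L
  }
  code_of <- function(snp) complete[snp, samples$cell_line]

  # ---- plant signals ------------------------------------------------------
  causal <- function(g) info$snp_id[info$host_gene == g][1]
  ladder <- cfg$signal_strength_ladder
  mult <- function(k) ladder[pmin(k, length(ladder))]
  mk_pairs <- function(genes, effect) {
    if (!length(genes))
      return(data.frame(snp_id = character(0), gene_id = character(0),
                        effect = numeric(0)))
    data.frame(snp_id = vapply(genes, causal, ""), gene_id = genes,
               effect = effect * mult(seq_along(genes)),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  eqtl_pairs <- mk_pairs(arch$eqtl_genes, cfg$beta_G_eqtl)
  sqtl_pairs <- mk_pairs(arch$sqtl_genes, cfg$gamma_interaction_sqtl)

  # ---- gene-level expression ----------------------------------------------
  gmu <- cfg$baseline_expr + stats::rnorm(cfg$n_genes, 0, 1)
  offs <- cfg$group_offsets[samples$group]
  sds <- cfg$group_residual_sd[samples$group]
  expr <- matrix(NA_real_, cfg$n_genes, ns,
                 dimnames = list(gm$gene_id, samples$sample_id))
  for (i in seq_len(cfg$n_genes)) {
    g <- gm$gene_id[i]
    mu <- gmu[i] + offs + b[samples$cell_line]
    hit <- eqtl_pairs$gene_id == g
    if (any(hit))
      mu <- mu + eqtl_pairs$effect[hit][1] * code_of(eqtl_pairs$snp_id[hit][1])
    for (a in arch$arch)
      if (a$mechanism == "expression" && g %in% a$targets)
        mu <- mu + a$effect * code_of(a$snp)
    expr[i, ] <- mu + stats::rnorm(ns, 0, sds)
  }

  # ---- exon counts --------------------------------------------------------
  lib_sizes <- round(cfg$lib_size_by_group[samples$group] *
                       exp(stats::rnorm(ns, 0, 0.1)))
  names(lib_sizes) <- samples$sample_id
  counts <- list(); lengths <- list()
  sqtl_contrast <- list()
  for (i in seq_len(cfg$n_genes)) {
    g <- gm$gene_id[i]
    ne <- gm$n_exons[i]
    st <- as.integer(strsplit(gm$exon_starts[i], ",")[[1]])
    en <- as.integer(strsplit(gm$exon_ends[i], ",")[[1]])
    len <- en - st + 1L
    a_e <- stats::runif(ne, 0.5, 1.5)
    a_e <- a_e / mean(a_e)
    d <- matrix(stats::rnorm(ne * nrow(cfg$group_layout), 0, 0.05),
                nrow(cfg$group_layout), ne,
                dimnames = list(cfg$group_layout$group, NULL))
    d <- d - rowMeans(d)
    idx <- matrix(rep(a_e, ns), ne, ns) + t(d[samples$group, , drop = FALSE])
    ctr <- rep(0, ne); ctr[1] <- 0.5; ctr[ne] <- -0.5
    hit <- sqtl_pairs$gene_id == g
    if (any(hit)) {
      code <- code_of(sqtl_pairs$snp_id[hit][1])
      idx <- idx + sqtl_pairs$effect[hit][1] * outer(ctr, code)
      sqtl_contrast[[g]] <- ctr
    }
    for (a in arch$arch)
      if (a$mechanism == "splicing" && g %in% a$targets)
        idx <- idx + a$effect * outer(ctr, code_of(a$snp))
    idx[idx < 0.05] <- 0.05
    lvl <- pmax(expr[i, ], 0.5)
    lam <- sweep(idx, 2, lvl * lib_sizes / 1e9, "*") * len
    cts <- matrix(stats::rpois(ne * ns, lam), ne, ns,
                  dimnames = list(sprintf("E%02d", seq_len(ne)),
                                  samples$sample_id))
    counts[[g]] <- cts
    lengths[[g]] <- stats::setNames(len, rownames(cts))
  }

  trans_edges <- do.call(rbind, lapply(arch$arch, function(a)
    data.frame(snp_id = a$snp,
               regulator = info$host_gene[match(a$snp, info$snp_id)],
               target = a$targets, mechanism = a$mechanism,
               effect = a$effect, stringsAsFactors = FALSE)))
  if (is.null(trans_edges))
    trans_edges <- data.frame(snp_id = character(0), regulator = character(0),
                              target = character(0), mechanism = character(0),
                              effect = numeric(0))
  # every trans edge's SNP must be cis to its regulator under the 20 kb rule
  if (nrow(trans_edges)) {
    ii <- match(trans_edges$snp_id, info$snp_id)
    gi <- match(trans_edges$regulator, gm$gene_id)
    stopifnot(all(info$pos[ii] >= gm$tx_start[gi] - 20000L &
                    info$pos[ii] <= gm$tx_end[gi] + 20000L))
  }

  truth <- list(eqtl_pairs = eqtl_pairs, sqtl_pairs = sqtl_pairs,
                trans_edges = trans_edges,
                variance_components = list(sigma_b2 = cfg$sigma_b^2,
                                           group_sd = cfg$group_residual_sd),
                null_genes = arch$null_genes,
                subject_effects = b, sqtl_contrast = sqtl_contrast)

  structure(list(samples = samples, expr = expr,
                 exons = list(counts = counts, lengths = lengths,
                              lib_sizes = lib_sizes),
                 truth = truth, gene_models = gm, genotypes = genotypes,
                 config = cfg),
            class = "sim_study")
}

#' One-call synthetic study
#'
#' Convenience wrapper: [simulate_genotypes()] then [simulate_expression()].
#' @param cfg a [sim_config()].
#' @export
simulate_qtl_study <- function(cfg = sim_config()) {
  simulate_expression(cfg, simulate_genotypes(cfg))
}

#' @export
print.sim_study <- function(x, ...) {
  cat("Synthetic QTL study:", nrow(x$samples), "samples /",
      length(unique(x$samples$cell_line)), "cell lines,",
      nrow(x$expr), "genes,", nrow(x$genotypes$codes), "SNPs\n")
  cat("Planted:", nrow(x$truth$eqtl_pairs), "eQTL,",
      nrow(x$truth$sqtl_pairs), "sQTL,",
      nrow(x$truth$trans_edges), "trans edges\n")
  invisible(x)
}

#' Rescaled exon index tensor from a study's counts
#'
#' Applies [exon_rpkm()] and [rescale_exon_index()] gene by gene.
#' @param exons the `exons` element of a [simulate_expression()] result (or
#'   any list with `counts`, `lengths`, `lib_sizes` of that shape).
#' @return named list: gene -> exons x samples index matrix.
#' @export
exon_index_tensor <- function(exons) {
  out <- lapply(names(exons$counts), function(g) {
    cts <- exons$counts[[g]]
    rp <- exon_rpkm(cts, exons$lengths[[g]][rownames(cts)],
                    rep(exons$lib_sizes[colnames(cts)], each = nrow(cts)))
    rescale_exon_index(rp)
  })
  names(out) <- names(exons$counts)
  out
}

#' Write the study's input files as TSVs
#'
#' Emits the pipeline's file interface: sample sheet, genotype code and SNP
#' position tables, per-sample library sizes, long-format exon counts with
#' lengths, a BED12-like gene model table and the planted-truth tables.
#'
#' @param study a `sim_study`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of written file paths.
#' @export
write_sim_inputs <- function(study, dir) {
  stopifnot(inherits(study, "sim_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) {
    p <- file.path(dir, f)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  write_genotype_tsv(study$genotypes, file.path(dir, "genotypes.tsv"),
                     file.path(dir, "snp_positions.tsv"))
  paths <- c(
    wt(study$samples, "samples.tsv"),
    file.path(dir, c("genotypes.tsv", "snp_positions.tsv")),
    wt(data.frame(sample_id = names(study$exons$lib_sizes),
                  mapped_reads = as.numeric(study$exons$lib_sizes)),
       "lib_sizes.tsv"),
    wt(do.call(rbind, lapply(names(study$exons$counts), function(g) {
      cts <- study$exons$counts[[g]]
      data.frame(gene_id = g, exon = rownames(cts),
                 length_nt = as.integer(study$exons$lengths[[g]][rownames(cts)]),
                 cts, check.names = FALSE, stringsAsFactors = FALSE)
    })), "exon_counts.tsv"),
    wt(study$gene_models, "gene_models.tsv"),
    wt(study$truth$eqtl_pairs, "truth_eqtl.tsv"),
    wt(study$truth$sqtl_pairs, "truth_sqtl.tsv"),
    wt(study$truth$trans_edges, "truth_trans.tsv"),
    wt(cbind(gene_id = rownames(study$expr), as.data.frame(study$expr)),
       "gene_expression.tsv"))
  invisible(paths)
}
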