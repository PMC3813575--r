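test_that("the generator is fully seed-deterministic", {
  cfg <- sim_config(seed = 5, n_genes = 8, n_snps = 40,
                    n_eqtl_genes = 2, n_sqtl_genes = 2)
  s1 <- simulate_qtl_study(cfg)
  s2 <- simulate_qtl_study(cfg)
  expect_identical(s1$genotypes$codes, s2$genotypes$codes)
  expect_identical(s1$expr, s2$expr)
  expect_identical(s1$exons$counts, s2$exons$counts)
  expect_identical(s1$samples, s2$samples)
  expect_identical(s1$truth$trans_edges, s2$truth$trans_edges)
  # a different seed changes the data
  s3 <- simulate_qtl_study(sim_config(seed = 6, n_genes = 8, n_snps = 40,
                                      n_eqtl_genes = 2, n_sqtl_genes = 2))
  expect_false(identical(s1$expr, s3$expr))
})

test_that("genotype class frequencies follow Hardy-Weinberg at the sampled MAF", {
  cfg <- sim_config(seed = 9, n_genes = 2, n_snps = 2,
                    maf_range = c(0.5, 0.5), missing_rate = 0,
                    n_cell_lines_per_population = c(pop1 = 5000, pop2 = 5000),
                    n_eqtl_genes = 0, n_sqtl_genes = 0, trans_arch = "none")
  g <- simulate_genotypes(cfg)
  fr <- table(g$codes[1, ]) / ncol(g$codes)
  # binomial 4-sigma tolerance at n = 10000
  expect_equal(unname(fr["0"]), 0.25, tolerance = 4 * sqrt(0.25 * 0.75 / 1e4) / 0.25)
  expect_equal(unname(fr["1"]), 0.50, tolerance = 4 * sqrt(0.5 * 0.5 / 1e4) / 0.5)
  expect_equal(unname(fr["2"]), 0.25, tolerance = 4 * sqrt(0.25 * 0.75 / 1e4) / 0.25)
})

test_that("LD blocks give correlated codes within and independence across blocks", {
  cfg <- sim_config(seed = 10, n_genes = 1, n_snps = 8, ld_block_size = 4,
                    ld_rho = 0.9, missing_rate = 0,
                    n_cell_lines_per_population = c(pop1 = 1500, pop2 = 10),
                    n_eqtl_genes = 0, n_sqtl_genes = 0, trans_arch = "none")
  g <- simulate_genotypes(cfg)
  r_within <- cor(g$codes[1, ], g$codes[2, ])
  r_across <- cor(g$codes[4, ], g$codes[5, ])   # last of block 1, first of block 2
  expect_gt(r_within, 0.5)
  expect_lt(abs(r_across), 0.1)
  # rho = 0: everything uncorrelated
  cfg0 <- sim_config(seed = 10, n_genes = 1, n_snps = 8, ld_block_size = 4,
                     ld_rho = 0, missing_rate = 0,
                     n_cell_lines_per_population = c(pop1 = 1500, pop2 = 10),
                     n_eqtl_genes = 0, n_sqtl_genes = 0, trans_arch = "none")
  g0 <- simulate_genotypes(cfg0)
  cc <- cor(t(g0$codes))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.1)
})

test_that("replicated samples share their cell line's genotype and subject effect", {
  study <- simulate_qtl_study(sim_config(seed = 11, n_genes = 8, n_snps = 24,
                                         n_eqtl_genes = 2, n_sqtl_genes = 2))
  sm <- study$samples
  dup <- sm$cell_line[duplicated(sm$cell_line)]
  expect_gt(length(dup), 0)
  # ~70% of lines are measured at least twice under the default layout
  frac_multi <- mean(table(sm$cell_line) >= 2)
  expect_equal(frac_multi, 0.7, tolerance = 0.01)
  # genotype codes are per line, so both samples of a line agree by
  # construction; subject effects likewise
  b <- study$truth$subject_effects
  expect_equal(length(b), length(unique(sm$cell_line)))
  # null-gene group variance approaches sigma_b^2 + group sd^2
  cfgv <- sim_config(seed = 12, n_genes = 2, n_snps = 4,
                     n_eqtl_genes = 0, n_sqtl_genes = 0, trans_arch = "none",
                     n_cell_lines_per_population = c(pop1 = 3000, pop2 = 10),
                     sigma_b = 1, group_residual_sd = c(A = 1.5, B1 = 2,
                                                        B2 = 2, C = 1.2))
  sv <- simulate_qtl_study(cfgv)
  yA <- sv$expr[1, sv$samples$group == "A"]
  expect_equal(var(yA), 1 + 1.5^2, tolerance = 0.12)
})

test_that("sigma_b = 0 removes the subject effect entirely", {
  study <- simulate_qtl_study(sim_config(seed = 13, n_genes = 6, n_snps = 12,
                                         sigma_b = 0, n_eqtl_genes = 0,
                                         n_sqtl_genes = 0, trans_arch = "none"))
  expect_true(all(study$truth$subject_effects == 0))
})

test_that("planted signals are recorded in the truth tables and carried by the data", {
  cfg <- sim_config(seed = 14)
  study <- simulate_qtl_study(cfg)
  tr <- study$truth
  expect_equal(nrow(tr$eqtl_pairs), cfg$n_eqtl_genes)
  expect_equal(nrow(tr$sqtl_pairs), cfg$n_sqtl_genes)
  expect_equal(nrow(tr$trans_edges), 16)
  # truth sets are disjoint from the designated null genes
  expect_length(intersect(tr$eqtl_pairs$gene_id, tr$null_genes), 0)
  expect_length(intersect(tr$sqtl_pairs$gene_id, tr$null_genes), 0)
  # every trans edge's SNP is cis to its regulator under the 20 kb rule
  gm <- study$gene_models
  info <- study$genotypes$info
  for (i in seq_len(nrow(tr$trans_edges))) {
    snp <- info[info$snp_id == tr$trans_edges$snp_id[i], ]
    gg <- gm[gm$gene_id == tr$trans_edges$regulator[i], ]
    expect_true(snp$pos >= gg$tx_start - 20000 & snp$pos <= gg$tx_end + 20000)
  }
  # the rescaled index of an sQTL gene regresses on genotype with the
  # planted contrast: slope on the contrast exon approximates the effect
  idx <- exon_index_tensor(study$exons)
  sq <- tr$sqtl_pairs[1, ]
  code <- attr(study$genotypes, "complete")[sq$snp_id,
                                            study$samples$cell_line]
  i1 <- idx[[sq$gene_id]][1, ]  # contrast +0.5 on the first exon
  sl <- coef(lm(i1 ~ code))[2]
  expect_equal(unname(sl), 0.5 * sq$effect, tolerance = 0.2)
  # expression of an eQTL gene carries the additive effect
  eq <- tr$eqtl_pairs[1, ]
  ce <- attr(study$genotypes, "complete")[eq$snp_id, study$samples$cell_line]
  sl2 <- coef(lm(study$expr[eq$gene_id, ] ~ ce))[2]
  expect_equal(unname(sl2), eq$effect, tolerance = 0.35)
})

test_that("invalid configurations and architectures are rejected", {
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(group_residual_sd = c(A = 0, B1 = 1, B2 = 1, C = 1)),
               "residual")
  expect_error(sim_config(ld_rho = 1), "ld_rho")
  cfg <- sim_config(seed = 1, n_genes = 6, n_snps = 12, n_eqtl_genes = 1,
                    n_sqtl_genes = 1,
                    trans_arch = list(list(snp = "nope", targets = "G05",
                                           effect = 1, mechanism = "expression")))
  expect_error(simulate_qtl_study(cfg), "unknown SNP")
  cfg2 <- sim_config(seed = 1, n_genes = 6, n_snps = 12, n_eqtl_genes = 1,
                     n_sqtl_genes = 1,
                     trans_arch = list(list(snp = "G01_s01", targets = "ZZ",
                                            effect = 1, mechanism = "expression")))
  expect_error(simulate_qtl_study(cfg2), "unknown target")
})

test_that("study input files are written as plain TSVs", {
  study <- simulate_qtl_study(sim_config(seed = 15, n_genes = 4, n_snps = 8,
                                         n_eqtl_genes = 1, n_sqtl_genes = 1))
  d <- withr::local_tempdir()
  paths <- write_sim_inputs(study, d)
  expect_true(all(file.exists(file.path(
    d, c("samples.tsv", "genotypes.tsv", "snp_positions.tsv",
         "exon_counts.tsv", "gene_models.tsv", "truth_eqtl.tsv",
         "gene_expression.tsv")))))
  sm <- read.table(file.path(d, "samples.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(sm), nrow(study$samples))
})
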