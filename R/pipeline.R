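#' Run the full cis/trans QTL-network pipeline on a study
#'
#' Executes the stages in dependency order: cis pair discovery, composite-LD
#' pruning, exon-index construction, the cis eQTL scan, the two-step cis
#' sQTL scan, the trans scans from called SNPs, genomic-region
#' classification of the cis calls, and paradigm/module network assembly.
#' When the study carries planted truth (a [simulate_expression()] result),
#' truth-versus-called confusion tables are added.  Reruns with the same
#' study and config are identical.
#'
#' @param study a `sim_study` (or any list with the same elements:
#'   `samples`, `expr`, `exons`, `genotypes`, `gene_models`, optionally
#'   `truth`).
#' @param config list of stage parameters; see [pipeline_config()].
#' @param out_dir optional directory: stage outputs are written as TSVs with
#'   a provenance manifest.
#' @return list of class `"qtl_pipeline"` with elements `cis`, `pruned`,
#'   `eqtl`, `sqtl`, `trans`, `cis_calls`, `trans_calls`, `regions`,
#'   `edges`, `modules`, `paradigm_summary`, `confusion` (when truth is
#'   available) and `manifest`.
#' @export
run_qtl_pipeline <- function(study, config = pipeline_config(),
                             out_dir = NULL) {
  stopifnot(is.list(study),
            all(c("samples", "expr", "exons", "genotypes", "gene_models")
                %in% names(study)))
  cf <- config
  geno <- study$genotypes

  cis <- find_cis_pairs(geno, study$gene_models, flank = cf$flank)
  pruned <- ld_prune(geno, cis$cis_sets, alpha = cf$prune_alpha)
  index <- exon_index_tensor(study$exons)

  eqtl <- scan_eqtl(geno, study$expr, study$samples, pruned$kept,
                    x = cf$fdr_eqtl, k = cf$k_eqtl, seed = cf$seed,
                    engine = "wlmm")
  sqtl <- scan_sqtl_two_step(geno, index, study$samples, pruned$kept,
                             x1 = cf$fdr_sqtl_step1, k1 = cf$k_sqtl_step1,
                             x2 = cf$fdr_sqtl_step2, k2 = cf$k_sqtl_step2,
                             seed = cf$seed + 101L)

  cis_calls <- rbind(
    if (nrow(eqtl$calls))
      data.frame(snp_id = eqtl$calls$snp_id, gene_id = eqtl$calls$gene_id,
                 mechanism = "expression", p = eqtl$calls$p,
                 stringsAsFactors = FALSE),
    if (nrow(sqtl$calls))
      data.frame(snp_id = sqtl$calls$snp_id, gene_id = sqtl$calls$gene_id,
                 mechanism = "splicing", p = sqtl$calls$p_model2b,
                 stringsAsFactors = FALSE))
  if (is.null(cis_calls))
    cis_calls <- data.frame(snp_id = character(0), gene_id = character(0),
                            mechanism = character(0), p = numeric(0))

  thresholds <- c(eqtl = unname(eqtl$threshold),
                  sqtl_step1 = unname(sqtl$threshold["step1"]),
                  sqtl_step2 = unname(sqtl$threshold["step2"]))
  trans <- if (nrow(cis_calls)) {
    scan_trans(unique(cis_calls$snp_id), geno, study$expr, index,
               study$samples, study$gene_models, thresholds,
               trans_dist = cf$trans_dist, flank = cf$flank,
               rule = cf$trans_sqtl_rule)
  } else list(calls = .empty_trans_calls(), tests = NULL)

  regions <- if (nrow(cis_calls))
    region_summary(cis_calls, geno, study$gene_models, flank = cf$flank)
  else NULL

  edges <- build_paradigms(cis_calls, trans$calls)
  modules <- build_modules(edges)
  psum <- summarize_paradigms(edges)

  confusion <- if (!is.null(study$truth))
    evaluate_against_truth(cis_calls, edges, study$truth) else NULL

  manifest <- list(
    package_version = as.character(utils::packageVersion("wlmmqtl")),
    config = cf, seed = cf$seed,
    config_checksum = .config_checksum(cf),
    n_samples = nrow(study$samples), n_genes = nrow(study$expr),
    n_snps = nrow(geno$codes),
    n_cis_pairs = nrow(cis$pairs),
    n_pruned_snps = sum(lengths(pruned$kept)),
    n_eqtl_calls = nrow(eqtl$calls), n_sqtl_calls = nrow(sqtl$calls),
    n_trans_calls = nrow(trans$calls), n_edges = nrow(edges),
    thresholds = thresholds)

  out <- list(cis = cis, pruned = pruned, eqtl = eqtl, sqtl = sqtl,
              trans = trans, cis_calls = cis_calls,
              trans_calls = trans$calls, regions = regions, edges = edges,
              modules = modules, paradigm_summary = psum,
              confusion = confusion, manifest = manifest)
  class(out) <- "qtl_pipeline"
  if (!is.null(out_dir)) .write_pipeline_outputs(out, out_dir)
  out
}

#' Pipeline stage parameters
#'
#' Defaults: 20 kb cis flank, 1 Mb trans distance, FDR targets 0.01 (eQTL),
#' 0.05/0.01 (sQTL steps 1/2), permutation counts 4/4/10, two-step
#' trans-splicing rule, LD pruning at adjusted p < 0.01.
#'
#' @param flank,trans_dist distances in nt.
#' @param fdr_eqtl,fdr_sqtl_step1,fdr_sqtl_step2 FDR targets in (0, 1).
#' @param k_eqtl,k_sqtl_step1,k_sqtl_step2 permutation counts.
#' @param prune_alpha LD pruning cutoff on the adjusted p-value.
#' @param trans_sqtl_rule `"two_step"` or `"model2b_only"`.
#' @param seed integer seed for all permutation draws.
#' @export
pipeline_config <- function(flank = 20000, trans_dist = 1e6,
                            fdr_eqtl = 0.01, fdr_sqtl_step1 = 0.05,
                            fdr_sqtl_step2 = 0.01, k_eqtl = 4,
                            k_sqtl_step1 = 4, k_sqtl_step2 = 10,
                            prune_alpha = 0.01,
                            trans_sqtl_rule = c("two_step", "model2b_only"),
                            seed = 1) {
  trans_sqtl_rule <- match.arg(trans_sqtl_rule)
  stopifnot(flank > 0, trans_dist > 0,
            fdr_eqtl > 0, fdr_eqtl < 1, fdr_sqtl_step1 > 0,
            fdr_sqtl_step1 < 1, fdr_sqtl_step2 > 0, fdr_sqtl_step2 < 1,
            k_eqtl >= 1, k_sqtl_step1 >= 1, k_sqtl_step2 >= 1,
            prune_alpha > 0, prune_alpha < 1)
  as.list(environment())
}

#' Compare pipeline calls with planted truth
#'
#' @param cis_calls data frame (`snp_id`, `gene_id`, `mechanism`).
#' @param edges output of [build_paradigms()].
#' @param truth the `truth` element of a `sim_study`.
#' @return list: `cis` (per class: planted genes, recovered genes,
#'   sensitivity, false gene calls), `trans` (per planted edge: recovered in
#'   the implied paradigm), `trans_sensitivity`.
#' @export
evaluate_against_truth <- function(cis_calls, edges, truth) {
  rec_gene <- function(mech) unique(cis_calls$gene_id[
    cis_calls$mechanism == mech])
  cis_eval <- function(pairs, mech) {
    planted <- unique(pairs$gene_id)
    rec <- rec_gene(mech)
    list(planted_genes = planted, recovered_genes = intersect(rec, planted),
         sensitivity = if (length(planted)) mean(planted %in% rec) else NA,
         false_genes = setdiff(rec, planted))
  }
  pmap <- c(expression.expression = "C1", splicing.expression = "C2",
            expression.splicing = "C3", splicing.splicing = "C4")
  te <- truth$trans_edges
  if (nrow(te)) {
    cis_mech <- ifelse(te$regulator %in% truth$eqtl_pairs$gene_id,
                       "expression", "splicing")
    te$paradigm <- unname(pmap[paste(cis_mech, te$mechanism, sep = ".")])
    te$recovered <- vapply(seq_len(nrow(te)), function(i)
      any(edges$regulator == te$regulator[i] &
            edges$target == te$target[i] &
            edges$paradigm == te$paradigm[i]), TRUE)
  }
  list(cis = list(eQTL = cis_eval(truth$eqtl_pairs, "expression"),
                  sQTL = cis_eval(truth$sqtl_pairs, "splicing")),
       trans = te,
       trans_sensitivity = if (nrow(te)) mean(te$recovered) else NA)
}

.config_checksum <- function(cf) {
  txt <- paste(deparse(cf[order(names(cf))]), collapse = "")
  v <- utf8ToInt(txt)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 2^31)
}

.write_pipeline_outputs <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) if (!is.null(x))
    utils::write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  wt(out$cis$pairs, "cis_pairs.tsv")
  kept <- data.frame(gene_id = rep(names(out$pruned$kept),
                                   lengths(out$pruned$kept)),
                     snp_id = unlist(out$pruned$kept, use.names = FALSE))
  wt(kept, "pruned_snps.tsv")
  wt(out$eqtl$tests, "eqtl_tests.tsv")
  wt(out$cis_calls, "cis_calls.tsv")
  wt(out$trans_calls, "trans_calls.tsv")
  if (!is.null(out$regions)) wt(out$regions$summary, "region_summary.tsv")
  wt(as.data.frame(out$edges), "network_edges.tsv")
  wt(out$modules, "network_modules.tsv")
  wt(out$paradigm_summary, "paradigm_summary.tsv")
  mf <- out$manifest
  writeLines(c(
    paste0("package_version\t", mf$package_version),
    paste0("seed\t", mf$seed),
    paste0("config_checksum\t", mf$config_checksum),
    paste0("thresholds\t", paste(names(mf$thresholds),
                                 signif(mf$thresholds, 6), sep = "=",
                                 collapse = ";")),
    paste0("rows\t", paste(
      c("cis_pairs", "eqtl_calls", "sqtl_calls", "trans_calls", "edges"),
      c(mf$n_cis_pairs, mf$n_eqtl_calls, mf$n_sqtl_calls, mf$n_trans_calls,
        mf$n_edges), sep = "=", collapse = ";"))),
    file.path(dir, "manifest.tsv"))
  invisible(out)
}

#' @export
print.qtl_pipeline <- function(x, ...) {
  mf <- x$manifest
  cat("QTL pipeline run:", mf$n_snps, "SNPs x", mf$n_genes, "genes,",
      mf$n_samples, "samples\n")
  cat("  cis calls:", mf$n_eqtl_calls, "eQTL,", mf$n_sqtl_calls, "sQTL;",
      "trans calls:", mf$n_trans_calls, "; edges:", mf$n_edges, "\n")
  if (!is.null(x$confusion))
    cat("  trans-edge sensitivity vs truth:",
        format(x$confusion$trans_sensitivity, digits = 3), "\n")
  invisible(x)
}
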