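#' Assemble cis-to-trans regulatory edges into the four network paradigms
#'
#' For every called cis (SNP, regulator gene) and every called trans
#' (same SNP, target gene), an edge regulator -> target is emitted in the
#' paradigm given by the cis mechanism crossed with the trans mechanism:
#' C1 = cisExpression_transExpression, C2 = cisSplicing_transExpression,
#' C3 = cisExpression_transSplicing, C4 = cisSplicing_transSplicing.
#' A SNP that is both a cis eQTL and a cis sQTL of its host contributes to
#' the paradigms of both cis mechanisms.  Edges are unique per
#' (regulator, target, paradigm); the mediating SNPs are collected per edge.
#'
#' @param cis_calls data frame of cis calls: `snp_id`, `gene_id`,
#'   `mechanism` ("expression" for eQTL, "splicing" for sQTL).
#' @param trans_calls data frame of trans calls: `snp_id`, `gene_id`
#'   (the target), `mechanism`.
#' @return data frame of class `"network_edges"`: `regulator`, `target`,
#'   `paradigm`, `snp_ids` (comma-joined mediators), `n_snps`.  A trans call
#'   whose SNP has no cis call is a hard error (it violates the mediation
#'   assumption the trans scan is built on).
#' @export
build_paradigms <- function(cis_calls, trans_calls) {
  stopifnot(all(c("snp_id", "gene_id", "mechanism") %in% names(cis_calls)),
            all(c("snp_id", "gene_id", "mechanism") %in% names(trans_calls)))
  if (nrow(trans_calls) == 0) return(.empty_edges())
  orphan <- setdiff(trans_calls$snp_id, cis_calls$snp_id)
  if (length(orphan))
    stop("trans call(s) mediated by SNP(s) without a cis call: ",
         paste(orphan, collapse = ", "))
  pmap <- c(expression.expression = "C1", splicing.expression = "C2",
            expression.splicing = "C3", splicing.splicing = "C4")
  rows <- list()
  for (i in seq_len(nrow(trans_calls))) {
    tc <- trans_calls[i, ]
    cc <- cis_calls[cis_calls$snp_id == tc$snp_id, ]
    for (j in seq_len(nrow(cc))) {
      if (cc$gene_id[j] == tc$gene_id) next   # regulator != target
      rows[[length(rows) + 1]] <- data.frame(
        regulator = cc$gene_id[j], target = tc$gene_id,
        paradigm = unname(pmap[paste(cc$mechanism[j], tc$mechanism,
                                     sep = ".")]),
        snp_id = tc$snp_id, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(.empty_edges())
  raw <- do.call(rbind, rows)
  key <- paste(raw$regulator, raw$target, raw$paradigm, sep = "\r")
  agg <- lapply(split(raw, key), function(d) data.frame(
    regulator = d$regulator[1], target = d$target[1],
    paradigm = d$paradigm[1],
    snp_ids = paste(sort(unique(d$snp_id)), collapse = ","),
    n_snps = length(unique(d$snp_id)), stringsAsFactors = FALSE))
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out <- out[order(out$paradigm, out$regulator, out$target), ]
  class(out) <- c("network_edges", "data.frame")
  out
}

.empty_edges <- function() {
  out <- data.frame(regulator = character(0), target = character(0),
                    paradigm = character(0), snp_ids = character(0),
                    n_snps = integer(0))
  class(out) <- c("network_edges", "data.frame")
  out
}

#' Hub modules: one cis-regulated gene and its trans targets
#'
#' Groups edges by (regulator, paradigm).  `n_snps` counts the distinct
#' mediating SNPs of the module and `n_targets` its distinct target genes;
#' modules are sorted by decreasing target count.
#'
#' @param edges output of [build_paradigms()].
#' @return data frame: `regulator`, `paradigm`, `n_snps`, `n_targets`,
#'   `targets` (comma-joined), `n_edges`.
#' @export
build_modules <- function(edges) {
  if (nrow(edges) == 0)
    return(data.frame(regulator = character(0), paradigm = character(0),
                      n_snps = integer(0), n_targets = integer(0),
                      targets = character(0), n_edges = integer(0)))
  key <- paste(edges$regulator, edges$paradigm, sep = "\r")
  out <- do.call(rbind, lapply(split(as.data.frame(edges), key), function(d) {
    snps <- unique(unlist(strsplit(d$snp_ids, ",", fixed = TRUE)))
    data.frame(regulator = d$regulator[1], paradigm = d$paradigm[1],
               n_snps = length(snps), n_targets = length(unique(d$target)),
               targets = paste(sort(unique(d$target)), collapse = ","),
               n_edges = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(-out$n_targets, out$paradigm, out$regulator), ]
}

#' Per-paradigm network summary
#'
#' One row per paradigm: distinct regulator genes, distinct target genes,
#' distinct mediating SNPs, connection counts, and the average number of
#' targets per regulator truncated to one decimal.  Connections are counted
#' two ways because the unit is convention-dependent: `n_connections`
#' counts distinct (regulator, target) gene pairs, and
#' `n_connections_snp` counts (SNP, regulator, target) triples.
#'
#' @param edges output of [build_paradigms()].
#' @return data frame with one row per paradigm present.
#' @export
summarize_paradigms <- function(edges) {
  if (nrow(edges) == 0)
    return(data.frame(paradigm = character(0), n_regulators = integer(0),
                      n_targets = integer(0), n_snps = integer(0),
                      n_connections = integer(0),
                      n_connections_snp = integer(0),
                      targets_per_regulator = numeric(0)))
  out <- do.call(rbind, lapply(split(as.data.frame(edges), edges$paradigm),
                               function(d) {
    snps <- unique(unlist(strsplit(d$snp_ids, ",", fixed = TRUE)))
    data.frame(paradigm = d$paradigm[1],
               n_regulators = length(unique(d$regulator)),
               n_targets = length(unique(d$target)),
               n_snps = length(snps),
               n_connections = nrow(d),
               n_connections_snp = sum(d$n_snps),
               targets_per_regulator = targets_per_regulator(
                 length(unique(d$target)), length(unique(d$regulator))),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Average targets per regulator, truncated to one decimal
#'
#' The headline per-paradigm ratio (e.g. 4040 targets over 241 regulators
#' gives 16.7) is conventionally printed truncated, not rounded.
#' @param n_targets,n_regulators counts.
#' @export
targets_per_regulator <- function(n_targets, n_regulators) {
  stopifnot(n_regulators > 0)
  trunc(10 * n_targets / n_regulators) / 10
}

#' Empirical CCDF of per-regulator target counts
#'
#' Orders regulators by decreasing target count, assigns integer indexes,
#' and computes the empirical complementary cumulative distribution
#' P(X > x) over x >= 1, optionally truncating counts above `truncation`
#' before the CCDF is computed (used to blunt the leverage of an extreme
#' hub when judging power-law resemblance on a double-log plot).
#'
#' @param modules output of [build_modules()] (optionally pre-filtered to
#'   one paradigm).
#' @param paradigm optional paradigm label to filter on.
#' @param truncation optional upper limit on counts; regulators with more
#'   targets are dropped before the CCDF is formed.
#' @return list of class `"target_ccdf"`: `ordered` (regulator, n_targets,
#'   index), `ccdf` (x, p = P(X > x), log10_x, log10_p with `-Inf` where
#'   p = 0).
#' @export
target_ccdf <- function(modules, paradigm = NULL, truncation = NULL) {
  if (!is.null(paradigm)) modules <- modules[modules$paradigm == paradigm, ]
  stopifnot(nrow(modules) >= 1)
  if (!is.null(truncation))
    modules <- modules[modules$n_targets <= truncation, ]
  stopifnot(nrow(modules) >= 1)
  counts <- modules$n_targets
  ord <- order(-counts)
  ordered <- data.frame(regulator = modules$regulator[ord],
                        n_targets = counts[ord],
                        index = seq_along(counts))
  xs <- sort(unique(counts))
  p <- vapply(xs, function(x) mean(counts > x), 0)
  out <- list(ordered = ordered,
              ccdf = data.frame(x = xs, p = p, log10_x = log10(xs),
                                log10_p = ifelse(p > 0, log10(p), -Inf)))
  class(out) <- "target_ccdf"
  out
}

#' @export
print.target_ccdf <- function(x, ...) {
  cat("Target-count CCDF over", nrow(x$ordered), "regulators; max count",
      max(x$ordered$n_targets), "\n")
  invisible(x)
}

#' @export
plot.target_ccdf <- function(x, ...) {
  ok <- is.finite(x$ccdf$log10_p)
  graphics::plot(x$ccdf$log10_x[ok], x$ccdf$log10_p[ok],
                 xlab = "log10 target count x", ylab = "log10 P(X > x)",
                 main = "Target-count CCDF", ...)
  invisible(x)
}
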