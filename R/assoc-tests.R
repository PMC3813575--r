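#' z-test for the additive genotype effect
#'
#' Tests \eqn{H_0: \beta_G = 0} for the single genotype-code coefficient of an
#' expression model (1a/1b/1c) with \eqn{z = \hat\beta_G / SE(\hat\beta_G)}
#' and a two-sided standard-normal p-value.  The normal reference is the
#' large-sample approximation appropriate when the number of subjects is
#' large; `q` is carried in the result so callers can warn at small q.
#'
#' @param fit a fitted [wlmm()] model containing the genotype term.
#' @param term name of the genotype term in the model formula
#'   (default `"geno"`); must map to exactly one estimated coefficient.
#' @return a one-row data frame of class `"assoc_test"`: `model`, `test`,
#'   `estimate`, `se`, `statistic`, `df1`, `p`, `converged`, `q`,
#'   `sigma_b2`, `sigma_e2`, `note`.
#' @export
test_genotype_effect <- function(fit, term = "geno") {
  stopifnot(inherits(fit, "wlmm"))
  idx <- .term_columns(fit, term)
  if (!fit$converged || length(idx) == 0)
    return(.assoc_row(fit, "z", NA, NA, NA, 1L, NA,
                      note = if (length(idx) == 0) "untestable" else "nonconverged"))
  if (length(idx) != 1)
    stop("term '", term, "' maps to ", length(idx),
         " coefficients; expected a single genotype code column")
  est <- fit$coefficients[idx]
  se <- fit$se[idx]
  if (!is.finite(se) || se <= 0)
    return(.assoc_row(fit, "z", est, se, NA, 1L, NA, note = "zero_se"))
  z <- est / se
  .assoc_row(fit, "z", est, se, z, 1L, 2 * stats::pnorm(-abs(z)))
}

#' Chi-squared (and exact F) test for the genotype-by-exon interaction
#'
#' Wald test of the genotype-by-exon coefficient block of a splicing model
#' (2a/2b).  The F statistic for the block is converted to
#' \eqn{X^2 = F \cdot v_1} and referred to a chi-squared distribution with
#' \eqn{v_1} (the number of estimable interaction coefficients) degrees of
#' freedom — the large-residual-df approximation.  For fixed-effects fits the
#' exact F p-value (with the residual df) is also recorded as `p_exact_f`.
#'
#' @param fit a fitted [wlmm()] splicing model.
#' @param term interaction term name (default `"geno:exon"`); matched against
#'   the model's term labels in either variable order.
#' @return one-row data frame as in [test_genotype_effect()] with
#'   `test = "chi2_from_F"`, `df1` \eqn{= v_1}, plus columns `f_statistic` and
#'   `p_exact_f`.
#' @export
test_interaction <- function(fit, term = "geno:exon") {
  stopifnot(inherits(fit, "wlmm"))
  idx <- .term_columns(fit, term)
  v1 <- length(idx)
  if (v1 == 0) {
    out <- .assoc_row(fit, "chi2_from_F", NA, NA, NA, 0L, NA, note = "untestable")
    out$f_statistic <- NA_real_; out$p_exact_f <- NA_real_
    return(out)
  }
  if (!fit$converged) {
    out <- .assoc_row(fit, "chi2_from_F", NA, NA, NA, v1, NA, note = "nonconverged")
    out$f_statistic <- NA_real_; out$p_exact_f <- NA_real_
    return(out)
  }
  b <- fit$coefficients[idx]
  V <- fit$vcov[idx, idx, drop = FALSE]
  Fstat <- tryCatch(drop(crossprod(b, solve(V, b))) / v1,
                    error = function(e) NA_real_)
  if (!is.finite(Fstat)) {
    out <- .assoc_row(fit, "chi2_from_F", NA, NA, NA, v1, NA, note = "singular_block")
    out$f_statistic <- NA_real_; out$p_exact_f <- NA_real_
    return(out)
  }
  x2 <- Fstat * v1
  p <- stats::pchisq(x2, df = v1, lower.tail = FALSE)
  out <- .assoc_row(fit, "chi2_from_F", NA, NA, x2, v1, p)
  out$f_statistic <- Fstat
  out$p_exact_f <- if (fit$model %in% c("hlm", "olm"))
    stats::pf(Fstat, v1, fit$df_residual, lower.tail = FALSE) else NA_real_
  out
}

#' Proportion of total variance from the subject random effect
#'
#' \eqn{\hat\sigma_b^2 / (\hat\sigma_b^2 + \hat\sigma_e^2)} from a converged
#' mixed-model fit.
#' @param fit a fitted [wlmm()] mixed model.
#' @export
variance_ratio <- function(fit) {
  stopifnot(inherits(fit, "wlmm"))
  if (fit$model != "wlmm" || !fit$converged) return(NA_real_)
  fit$sigma_b2 / (fit$sigma_b2 + fit$sigma_e2)
}

.term_columns <- function(fit, term) {
  labs <- attr(fit$terms, "term.labels")
  hit <- which(labs == term)
  if (length(hit) == 0) {
    # accept the reversed interaction order, e.g. "exon:geno"
    flip <- paste(rev(strsplit(term, ":", fixed = TRUE)[[1]]), collapse = ":")
    hit <- which(labs == flip)
  }
  if (length(hit) == 0) return(integer(0))
  which(fit$assign == hit[1])
}

.assoc_row <- function(fit, test, est, se, stat, df1, p, note = "") {
  data.frame(model = fit$model, test = test,
             estimate = unname(est), se = unname(se),
             statistic = unname(stat), df1 = df1, p = unname(p),
             converged = fit$converged, q = fit$q,
             sigma_b2 = fit$sigma_b2, sigma_e2 = fit$sigma_e2,
             note = note, stringsAsFactors = FALSE)
}

#' Compare the mixed, heteroscedastic and ordinary fits across gene::SNP pairs
#'
#' For each supplied design, fits the mixed model (REML), the weighted
#' fixed-effects model and the unweighted fixed-effects model, and tabulates
#' AIC for all three plus adjusted R-squared for the two fixed-effects fits.
#' Adjusted R-squared is intentionally not reported for the mixed model
#' (the criterion is not recommended for evaluating mixed models), and
#' cross-family AIC comparisons are heuristic: the mixed-model AIC comes from
#' the REML objective while the fixed-effects AICs come from Gaussian ML.
#'
#' @param designs a list of data frames, each with columns `y`, `group`,
#'   `subject`, `geno` (one gene::SNP pair per element); names are carried to
#'   the output.
#' @param weights_by how to compute the weights for the weighted fits, see
#'   [compute_weights()]; the default recomputes per-group inverse-variance
#'   weights from each design's response.
#' @return list with `table` (one row per pair: AICs, adjusted R-squared,
#'   convergence) and `summary` (fractions of converged pairs for which each
#'   criterion favours each model, plus the non-converged count).
#' @export
compare_models <- function(designs, weights_by = "per_group") {
  stopifnot(is.list(designs), length(designs) > 0)
  rows <- lapply(seq_along(designs), function(i) {
    d <- designs[[i]]
    w <- compute_weights(d$y, d$group, mode = weights_by)$weight
    d$.w <- w
    fw <- wlmm(y ~ 0 + group + geno, d, subject = "subject", weights = ".w")
    fh <- wlmm(y ~ 0 + group + geno, d, weights = ".w")
    fo <- wlmm(y ~ 0 + group + geno, d)
    data.frame(pair = if (!is.null(names(designs))) names(designs)[i] else
                 as.character(i),
               aic_wlmm = fw$aic, aic_hlm = fh$aic, aic_olm = fo$aic,
               adj_r2_hlm = fh$adj_r_squared, adj_r2_olm = fo$adj_r_squared,
               wlmm_converged = fw$converged, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ok <- tab$wlmm_converged & is.finite(tab$aic_wlmm)
  summary <- list(
    n_pairs = nrow(tab),
    n_nonconverged = sum(!ok),
    frac_aic_hlm_lt_olm = mean(tab$aic_hlm < tab$aic_olm),
    frac_adj_r2_hlm_gt_olm = mean(tab$adj_r2_hlm > tab$adj_r2_olm),
    frac_aic_wlmm_lt_hlm = if (any(ok))
      mean(tab$aic_wlmm[ok] < tab$aic_hlm[ok]) else NA_real_)
  list(table = tab, summary = summary)
}
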