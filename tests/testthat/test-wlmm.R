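test_that("ordinary least squares matches the normal-equations oracle on hand data", {
  d <- data.frame(y = c(1.2, 2.1, 2.9, 4.2, 4.8, 6.1),
                  group = factor(rep("A", 6)), geno = c(0, 0, 1, 1, 2, 2))
  fit <- wlmm(y ~ 0 + group + geno, d)
  X <- cbind(1, d$geno)
  or <- oracle_wls(X, d$y, rep(1, 6))
  expect_equal(unname(coef(fit)), or$beta, tolerance = 1e-10)
  expect_equal(unname(fit$se), or$se, tolerance = 1e-10)
  # permuting row order changes nothing
  fit2 <- wlmm(y ~ 0 + group + geno, d[c(4, 1, 6, 2, 5, 3), ])
  expect_equal(coef(fit2), coef(fit), tolerance = 1e-12)
  expect_equal(fit2$aic, fit$aic, tolerance = 1e-12)
  # exactly linear response gives adjusted R^2 = 1
  d$y <- 1 + 2 * d$geno
  expect_equal(wlmm(y ~ 0 + group + geno, d)$adj_r_squared, 1)
})

test_that("weighted least squares matches the weighted normal-equations oracle", {
  d <- data.frame(y = c(1, 3, 2, 5), geno = c(0, 1, 2, 2),
                  group = factor("A"), w = c(1, 1, 4, 4))
  fit <- wlmm(y ~ 0 + group + geno, d, weights = "w")
  or <- oracle_wls(cbind(1, d$geno), d$y, d$w)
  expect_equal(unname(coef(fit)), or$beta, tolerance = 1e-10)
  expect_equal(fit$model, "hlm")
})

test_that("reduction identities: equal weights collapse HLM to OLM, and sigma_b^2 = 0 collapses the mixed model to OLS", {
  d <- sim_trait(11, n_lines = 20, beta = 0.5)
  d$w1 <- rep(1, nrow(d))
  fo <- wlmm(y ~ 0 + group + geno, d)
  fh <- wlmm(y ~ 0 + group + geno, d, weights = "w1")
  expect_equal(coef(fh), coef(fo), tolerance = 1e-8)
  expect_equal(fh$sigma_e2, fo$sigma_e2, tolerance = 1e-8)
  expect_equal(fh$logLik, fo$logLik, tolerance = 1e-8)
  # pin sigma_b^2 = 0
  fw <- wlmm(y ~ 0 + group + geno, d, subject = "subject", weights = "w1",
             control = wlmm_control(fix_lambda = 0))
  expect_true(fw$boundary)
  expect_equal(fw$sigma_b2, 0)
  expect_equal(coef(fw), coef(fo), tolerance = 1e-8)
  expect_equal(fw$sigma_e2, fo$sigma_e2, tolerance = 1e-8)
})

test_that("REML components match the balanced one-way ANOVA estimators", {
  set.seed(21)
  q <- 12; k <- 3
  subj <- rep(seq_len(q), each = k)
  y <- rnorm(q, 0, 1.5)[subj] + rnorm(q * k, 0, 1)
  d <- data.frame(y = y, subject = factor(subj))
  fit <- wlmm(y ~ 1, d, subject = "subject")
  or <- oracle_anova_vc(y, subj, k)
  expect_equal(fit$sigma_e2, or$sigma_e2, tolerance = 1e-6)
  expect_equal(fit$sigma_b2, or$sigma_b2, tolerance = 1e-6)
  # grand mean is the fixed effect in the balanced design
  expect_equal(unname(coef(fit)), mean(y), tolerance = 1e-8)

  # truncation at zero: no subject variance in truth, unbalanced replication
  d0 <- sim_trait(31, n_lines = 25, sigma_b = 0)
  f0 <- fit_model1a(d0)
  expect_gte(f0$sigma_b2, 0)
  expect_lt(variance_ratio(f0), 0.15)
})

test_that("the GLS oracle is reproduced when the variance ratio is pinned", {
  d <- sim_trait(7, n_lines = 12, beta = 1, sigma_b = 1.2)
  d$.w <- compute_weights(d$y, d$group)$weight
  lam <- 1.7
  fit <- wlmm(y ~ 0 + group + geno, d, subject = "subject", weights = ".w",
              control = wlmm_control(fix_lambda = lam))
  X <- cbind(d$group == "A", d$group == "B", d$geno) * 1
  beta_gls <- oracle_gls(X, d$y, d$.w, as.integer(d$subject),
                         sigma_b2 = lam, sigma_e2 = 1)
  expect_equal(unname(coef(fit)), beta_gls, tolerance = 1e-6)
})

test_that("the in-package REML fit agrees with lmer on a replicated heteroscedastic dataset", {
  library(lme4)
  d <- sim_trait(3, n_lines = 40, beta = 0.7, sigma_b = 1.3)
  d$.w <- compute_weights(d$y, d$group)$weight
  fit <- wlmm(y ~ 0 + group + geno, d, subject = "subject", weights = ".w")
  lf <- lmer(y ~ 0 + group + geno + (1 | subject), d, weights = d$.w,
             REML = TRUE)
  expect_equal(unname(coef(fit)), unname(fixef(lf)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(as.matrix(vcov(lf))))),
               tolerance = 1e-5)
  vc <- as.data.frame(VarCorr(lf))$vcov
  expect_equal(fit$sigma_b2, vc[1], tolerance = 1e-5)
  expect_equal(fit$sigma_e2, vc[2], tolerance = 1e-5)
  expect_equal(-2 * fit$logLik, REMLcrit(lf), tolerance = 1e-6)
})

test_that("REML log-likelihood at the optimum is no worse than at the truth", {
  for (s in 1:5) {
    d <- sim_trait(s + 100, n_lines = 30, beta = 0.5, sigma_b = 1)
    d$.w <- compute_weights(d$y, d$group)$weight
    fit <- wlmm(y ~ 0 + group + geno, d, subject = "subject", weights = ".w")
    ss <- wlmmqtl:::.reml_suffstat(
      stats::model.matrix(~ 0 + group + geno, d), d$y, d$.w, d$subject)
    at_truth <- wlmmqtl:::.reml_eval(ss, 1)     # true sigma_b2/sigma_e2 = 1
    expect_lte(-2 * fit$logLik, at_truth$crit + 1e-6)
  }
})

test_that("z-test of the genotype effect: definition, quantile oracle and edge cases", {
  d <- sim_trait(13, n_lines = 30, beta = 0.8)
  fit <- fit_model1a(d)
  tst <- test_genotype_effect(fit)
  expect_equal(tst$statistic, unname(coef(fit)["geno"] / fit$se["geno"]))
  expect_equal(tst$p, 2 * pnorm(-abs(tst$statistic)))
  # z at the 97.5% normal quantile gives p = 0.05
  expect_equal(2 * pnorm(-1.959964), 0.05, tolerance = 1e-6)
  # estimate of exactly zero gives p = 1 (constructed via orthogonal response)
  d2 <- data.frame(y = c(1, -1, 1, -1), group = factor("A"),
                   geno = c(0, 0, 2, 2))
  f2 <- wlmm(y ~ 0 + group + geno, d2)
  expect_equal(test_genotype_effect(f2)$p, 1)
  # constant genotype column is aliased away -> untestable
  d3 <- data.frame(y = rnorm(8), group = factor("A"), geno = rep(1, 8))
  f3 <- suppressWarnings(wlmm(y ~ 0 + group + geno, d3))
  expect_equal(test_genotype_effect(f3)$note, "untestable")
})

test_that("interaction test: X^2 = F * v1 against the chi-squared tail, with the exact F recorded for fixed-effects fits", {
  # fabricated fit with identity vcov: F = b'b / v1 exactly
  fk <- structure(list(
    coefficients = c(g1 = 1, g2 = 1, `geno:exonE1` = sqrt(2.5),
                     `geno:exonE2` = sqrt(2.5), `geno:exonE3` = sqrt(2.5),
                     `geno:exonE4` = sqrt(2.5)),
    se = rep(1, 6), vcov = diag(6), converged = TRUE, q = 50,
    sigma_b2 = 0, sigma_e2 = 1, model = "hlm", df_residual = 400,
    assign = c(1, 1, 2, 2, 2, 2),
    terms = terms(y ~ 0 + g + geno:exon)), class = "wlmm")
  tst <- test_interaction(fk, term = "geno:exon")
  expect_equal(tst$df1, 4)
  expect_equal(tst$f_statistic, 2.5, tolerance = 1e-12)
  expect_equal(tst$statistic, 10, tolerance = 1e-12)
  expect_equal(tst$p, pchisq(10, 4, lower.tail = FALSE))
  expect_equal(tst$p, 0.04042768, tolerance = 1e-7)
  expect_equal(tst$p_exact_f, pf(2.5, 4, 400, lower.tail = FALSE))

  # F = 0 gives X^2 = 0 and p = 1
  f0 <- fk; f0$coefficients[3:6] <- 0
  expect_equal(test_interaction(f0)$p, 1)

  # chi-squared approximation converges to the exact F p-value as the
  # residual df grow
  f_big <- fk; f_big$df_residual <- 1e4
  t_big <- test_interaction(f_big)
  expect_lt(abs(t_big$p - t_big$p_exact_f), 1e-3)
})

test_that("variance ratio reports sigma_b2 / (sigma_b2 + sigma_e2)", {
  d <- sim_trait(17, n_lines = 40, sigma_b = 1)
  fit <- fit_model1a(d)
  expect_equal(variance_ratio(fit),
               fit$sigma_b2 / (fit$sigma_b2 + fit$sigma_e2))
  d0 <- sim_trait(18, n_lines = 20)
  f0 <- wlmm(y ~ 0 + group + geno, d0)
  expect_true(is.na(variance_ratio(f0)))   # fixed-effects fit
})

test_that("empirical power of the z-test is non-decreasing in the effect size", {
  betas <- c(0, 0.25, 0.5, 1.0)
  power <- vapply(betas, function(b) {
    mean(vapply(1:60, function(s)
      test_genotype_effect(fit_model1a(sim_trait(s, n_lines = 60,
                                                 beta = b)))$p < 0.05,
      TRUE))
  }, 0)
  expect_true(all(diff(power) >= 0))
  expect_lt(power[1], 0.15)
  expect_gt(power[4], 0.9)
})

test_that("model comparison reproduces AIC arithmetic and the expected regimes", {
  # hand AIC: -2 logLik + 2k on a single fixed-effects pair
  d <- sim_trait(23, n_lines = 15, beta = 0.5)
  fo <- wlmm(y ~ 0 + group + geno, d)
  expect_equal(fo$aic, -2 * fo$logLik + 2 * (fo$p + 1), tolerance = 1e-10)
  expect_equal(AIC(logLik(fo)), fo$aic, tolerance = 1e-10)

  # heteroscedastic + replicated: the mixed model wins AIC for most pairs
  designs <- lapply(1:40, function(s)
    sim_trait(s + 500, n_lines = 50, beta = 0.3, sigma_b = 1.5))
  cmp <- compare_models(designs)
  expect_gt(cmp$summary$frac_aic_wlmm_lt_hlm, 0.5)
  expect_gt(cmp$summary$frac_aic_hlm_lt_olm, 0.5)
  expect_equal(cmp$summary$n_pairs, 40)

  # homoscedastic, unreplicated: weighted and ordinary fits nearly coincide
  designs0 <- lapply(1:20, function(s)
    sim_trait(s + 900, n_lines = 40, sd_groups = c(A = 1, B = 1),
              sigma_b = 0, rep_frac = 0))
  cmp0 <- compare_models(designs0)
  expect_lt(median(abs(cmp0$table$aic_hlm - cmp0$table$aic_olm)), 2)
  expect_false("adj_r2_wlmm" %in% names(cmp0$table))
})

test_that("prediction, simulation and residual methods are coherent", {
  d <- sim_trait(29, n_lines = 25, beta = 1, sigma_b = 1)
  fit <- fit_model1a(d)
  expect_equal(predict(fit), fitted(fit))
  expect_equal(unname(predict(fit, newdata = d)), unname(fitted(fit)),
               tolerance = 1e-10)
  # conditional residuals remove the subject effects
  rc <- residuals(fit, type = "conditional")
  rm_ <- residuals(fit)
  expect_equal(rm_ - rc, fit$ranef[as.integer(fit$subject)],
               ignore_attr = TRUE)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(nrow(d), 3))
  expect_false(any(is.na(sims)))
})
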