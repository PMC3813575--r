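#' @export
print.wlmm <- function(x, digits = max(3L, getOption("digits") - 3L), ...) {
  lab <- c(wlmm = "Weighted linear mixed model (REML)",
           hlm = "Heteroscedastic linear model (WLS)",
           olm = "Ordinary linear model (OLS)")[x$model]
  cat(lab, "\n")
  cat("Call: ", deparse(x$call), "\n\n")
  print(round(x$coefficients, digits))
  if (x$model == "wlmm") {
    cat("\nsigma_b^2 =", format(x$sigma_b2, digits = digits),
        " sigma_e^2 =", format(x$sigma_e2, digits = digits),
        " (", x$q, "subjects )\n")
    if (x$boundary) cat("note: REML optimum at sigma_b^2 = 0 (boundary)\n")
    if (!x$converged) cat("note: fit did not converge\n")
  } else {
    cat("\nresidual variance =", format(x$sigma_e2, digits = digits), "\n")
  }
  invisible(x)
}

#' @export
summary.wlmm <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(call = object$call, model = object$model, coefficients = tab,
              sigma_b2 = object$sigma_b2, sigma_e2 = object$sigma_e2,
              variance_ratio = if (object$model == "wlmm")
                variance_ratio(object) else NA_real_,
              aic = object$aic, adj_r_squared = object$adj_r_squared,
              logLik = object$logLik, reml = object$reml,
              n = object$n, q = object$q, converged = object$converged,
              boundary = object$boundary)
  class(out) <- "summary.wlmm"
  out
}

#' @export
print.summary.wlmm <- function(x, digits = max(3L, getOption("digits") - 3L),
                               ...) {
  cat("Model:", x$model, "  n =", x$n,
      if (x$model == "wlmm") paste(" subjects =", x$q), "\n")
  stats::printCoefmat(x$coefficients, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE)
  if (x$model == "wlmm") {
    cat("\nVariance components: sigma_b^2 =", format(x$sigma_b2, digits = digits),
        " sigma_e^2 =", format(x$sigma_e2, digits = digits),
        " ratio =", format(x$variance_ratio, digits = digits), "\n")
  } else {
    cat("\nAdj. R-squared:", format(x$adj_r_squared, digits = digits), "\n")
  }
  cat("AIC:", format(x$aic, digits = digits),
      if (x$reml) "(from the REML objective)", "\n")
  invisible(x)
}

#' @export
coef.wlmm <- function(object, ...) object$coefficients

#' @export
vcov.wlmm <- function(object, ...) object$vcov

#' @export
fitted.wlmm <- function(object, ...) object$fitted

#' @export
residuals.wlmm <- function(object, type = c("marginal", "conditional"), ...) {
  type <- match.arg(type)
  r <- object$residuals
  if (type == "conditional" && !is.null(object$ranef))
    r <- r - object$ranef[as.integer(object$subject)]
  r
}

#' @export
logLik.wlmm <- function(object, ...) {
  val <- object$logLik
  attr(val, "df") <- object$p + if (object$model == "wlmm") 2L else 1L
  attr(val, "nobs") <- object$n
  class(val) <- "logLik"
  val
}

#' @export
nobs.wlmm <- function(object, ...) object$n

#' Predict from a fitted model
#'
#' @param object a fitted [wlmm()] model.
#' @param newdata optional data frame of covariates; the fitted values are
#'   returned when omitted.
#' @param level 0 for population-level (fixed effects only) predictions, 1 to
#'   add the estimated subject effects (subjects unseen at fit time get 0).
#' @param ... unused.
#' @export
predict.wlmm <- function(object, newdata = NULL, level = 0, ...) {
  if (is.null(newdata)) {
    pr <- object$fitted
    if (level >= 1 && !is.null(object$ranef))
      pr <- pr + object$ranef[as.integer(object$subject)]
    return(pr)
  }
  tt <- stats::delete.response(object$terms)
  mf <- stats::model.frame(tt, newdata, na.action = stats::na.pass)
  X <- stats::model.matrix(tt, mf)
  miss <- setdiff(names(object$coefficients), colnames(X))
  if (length(miss))
    stop("newdata does not span fitted coefficients: ",
         paste(miss, collapse = ", "))
  X <- X[, names(object$coefficients), drop = FALSE]
  pr <- drop(X %*% object$coefficients)
  if (level >= 1 && !is.null(object$ranef)) {
    sc <- object$call$subject
    nm <- if (is.character(sc)) sc else NULL
    if (!is.null(nm) && nm %in% names(newdata)) {
      b <- object$ranef[as.character(newdata[[nm]])]
      b[is.na(b)] <- 0
      pr <- pr + b
    }
  }
  pr
}

#' Simulate responses from a fitted model
#'
#' Draws new response vectors from the estimated Gaussian model
#' (new subject effects and residuals at the estimated variance components).
#' @param object a fitted [wlmm()] model.
#' @param nsim number of simulated response vectors.
#' @param seed optional integer seed.
#' @param ... unused.
#' @export
simulate.wlmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n
  out <- as.data.frame(matrix(NA_real_, n, nsim))
  names(out) <- paste0("sim_", seq_len(nsim))
  sdres <- sqrt(object$sigma_e2 / object$weights)
  for (j in seq_len(nsim)) {
    y <- object$fitted + stats::rnorm(n, 0, sdres)
    if (object$model == "wlmm" && object$sigma_b2 > 0) {
      b <- stats::rnorm(object$q, 0, sqrt(object$sigma_b2))
      y <- y + b[as.integer(object$subject)]
    }
    out[[j]] <- y
  }
  out
}

#' @export
plot.wlmm <- function(x, ...) {
  graphics::plot(x$fitted, x$residuals * sqrt(x$weights),
                 xlab = "Fitted values", ylab = "Weighted residuals",
                 main = paste("Residuals,", x$model), ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
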