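# log(1 + exp(x)) without overflow for large |x|
.log1pexp <- function(x) {
  out <- numeric(length(x))
  big <- x > 33.3
  mid <- !big & x > -37
  out[big] <- x[big]
  out[mid] <- log1p(exp(x[mid]))
  out[!big & !mid] <- exp(x[!big & !mid])
  out
}

# sigmoid evaluated as a symmetric (mu, 1-mu) pair from |eta|, so that
# negating eta swaps the two values bitwise. This makes the label-swap and
# sign-flip antisymmetries of the fit exact in IEEE arithmetic instead of
# merely approximate.
.sigmoid_pair <- function(eta) {
  a <- exp(-abs(eta))
  hi <- 1 / (1 + a)     # sigmoid(|eta|)
  lo <- a / (1 + a)     # sigmoid(-|eta|)
  pos <- eta >= 0
  mu <- ifelse(pos, hi, lo)
  q <- ifelse(pos, lo, hi)
  list(mu = mu, q = q)
}

#' Log-likelihood of the membership logistic model
#'
#' The Bernoulli log-likelihood of membership labels y under the sigmoid
#' hypothesis P(member | x) = 1 / (1 + exp(-(theta0 + theta1 x))):
#' \deqn{\ell(\theta) = \sum_i y_i \log h_\theta(x_i) +
#'   (1 - y_i)\log(1 - h_\theta(x_i)),}
#' evaluated in a numerically stable form so linear predictors of magnitude
#' up to several hundred neither overflow nor produce NaN.
#'
#' @param theta Numeric length-2 vector `(theta0, theta1)`.
#' @param x Numeric predictor vector (per-gene impact scores).
#' @param y 0/1 membership labels, same length as `x`.
#' @return The log-likelihood (a single number, <= 0).
#' @export
loglik_logistic <- function(theta, x, y) {
  stopifnot(length(theta) == 2L, length(x) == length(y))
  eta <- theta[1L] + theta[2L] * x
  # y=1 term: log mu = -log1pexp(-eta); y=0 term: log(1-mu) = -log1pexp(eta)
  -sum(.log1pexp(ifelse(y == 1, -eta, eta)))
}

# gradient of loglik_logistic: t(X) %*% (y - mu), with the symmetric residual
.loglik_grad <- function(theta, x, y) {
  eta <- theta[1L] + theta[2L] * x
  sp <- .sigmoid_pair(eta)
  r <- ifelse(y == 1, sp$q, -sp$mu)       # y - mu, exact under label swap
  c(sum(r), sum(r * x))
}

#' Fit the membership logistic regression by Fisher scoring (IWLS)
#'
#' Iteratively reweighted least squares for the two-parameter logistic model
#' of [loglik_logistic()]: starting from (0, 0), each step forms the working
#' weights mu(1-mu) and working response eta + (y - mu)/(mu(1-mu)) and solves
#' the 2x2 weighted least-squares system in closed form; iteration stops when
#' the relative deviance change drops below `tol`. The covariance of the
#' estimate is the inverse of the final weighted information matrix.
#'
#' @param x Numeric predictor vector.
#' @param y 0/1 membership labels.
#' @param tol Convergence tolerance on the relative deviance change.
#' @param max_iter Maximum number of Fisher-scoring iterations.
#' @return A `logit_fit`: list with `theta` (named length-2), `covariance`
#'   (2x2), `se` (named), `loglik`, `deviance`, `converged`, `iterations`,
#'   `reason` (non-NULL when not converged) and `optimizer = "IWLS"`.
#' @export
fit_iwls <- function(x, y, tol = 1e-8, max_iter = 25L) {
  design <- .check_design(x, y)
  x <- design$x; y <- design$y
  n <- length(y)
  theta0 <- 0; theta1 <- 0
  dev_old <- Inf
  converged <- FALSE
  reason <- NULL
  iter <- 0L
  Sw <- Sx <- Sxx <- det <- NA_real_
  for (iter in seq_len(max_iter)) {
    eta <- theta0 + theta1 * x
    sp <- .sigmoid_pair(eta)
    w <- pmax(sp$mu * sp$q, 1e-10)
    r <- ifelse(y == 1, sp$q, -sp$mu)     # y - mu
    z <- eta + r / w
    Sw <- sum(w); Sx <- sum(w * x); Sxx <- sum(w * x * x)
    Sy <- sum(w * z); Sxy <- sum(w * x * z)
    det <- Sw * Sxx - Sx * Sx
    if (!is.finite(det) || det <= Sw * Sxx * 1e-12 || det == 0) {
      reason <- "singular information matrix (predictor nearly constant)"
      break
    }
    theta1 <- (Sw * Sxy - Sx * Sy) / det
    theta0 <- (Sxx * Sy - Sx * Sxy) / det
    dev <- -2 * loglik_logistic(c(theta0, theta1), x, y)
    if (is.finite(dev_old) &&
        abs(dev - dev_old) / (abs(dev) + 0.1) < tol) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  if (!converged && is.null(reason)) {
    reason <- paste0("no convergence in ", max_iter, " iterations")
  }
  if (is.finite(det) && det > 0) {
    # information re-evaluated at the final estimate (the loop's last system
    # used the weights of the previous iterate)
    eta <- theta0 + theta1 * x
    sp <- .sigmoid_pair(eta)
    w <- pmax(sp$mu * sp$q, 1e-10)
    Sw <- sum(w); Sx <- sum(w * x); Sxx <- sum(w * x * x)
    det <- Sw * Sxx - Sx * Sx
  }
  covariance <- if (is.finite(det) && det > 0) {
    matrix(c(Sxx, -Sx, -Sx, Sw) / det, 2L, 2L,
           dimnames = list(c("theta0", "theta1"), c("theta0", "theta1")))
  } else {
    matrix(NA_real_, 2L, 2L,
           dimnames = list(c("theta0", "theta1"), c("theta0", "theta1")))
  }
  .logit_fit(c(theta0, theta1), covariance,
             loglik = loglik_logistic(c(theta0, theta1), x, y),
             converged = converged, iterations = iter,
             optimizer = "IWLS", reason = reason)
}

#' Fit the membership logistic regression by quasi-Newton optimisation
#'
#' Maximises [loglik_logistic()] directly (via [stats::optim()] on its
#' negation) with the analytic gradient, starting from (0, 0). The covariance
#' is the inverse observed information at the optimum (which equals the
#' expected information for the logistic model).
#'
#' @param x Numeric predictor vector.
#' @param y 0/1 membership labels.
#' @param method `"BFGS"` or `"L-BFGS-B"`.
#' @param tol Relative convergence tolerance passed to the optimiser.
#' @param max_iter Maximum optimiser iterations.
#' @return A `logit_fit` (see [fit_iwls()]); `iterations` is the number of
#'   gradient evaluations reported by the optimiser.
#' @export
fit_optim <- function(x, y, method = c("BFGS", "L-BFGS-B"),
                      tol = 1e-10, max_iter = 200L) {
  method <- match.arg(method)
  design <- .check_design(x, y)
  x <- design$x; y <- design$y
  nll <- function(th) -loglik_logistic(th, x, y)
  ngr <- function(th) -.loglik_grad(th, x, y)
  ctrl <- list(maxit = max_iter)
  if (method == "BFGS") ctrl$reltol <- tol else ctrl$factr <- tol / 1e-15
  res <- tryCatch(
    stats::optim(c(0, 0), nll, ngr, method = method, control = ctrl),
    error = function(e) e
  )
  dn <- list(c("theta0", "theta1"), c("theta0", "theta1"))
  if (inherits(res, "error")) {
    return(.logit_fit(c(NA_real_, NA_real_),
                      matrix(NA_real_, 2, 2, dimnames = dn),
                      loglik = NA_real_, converged = FALSE, iterations = 0L,
                      optimizer = method, reason = conditionMessage(res)))
  }
  theta <- res$par
  eta <- theta[1L] + theta[2L] * x
  sp <- .sigmoid_pair(eta)
  w <- sp$mu * sp$q
  Sw <- sum(w); Sx <- sum(w * x); Sxx <- sum(w * x * x)
  det <- Sw * Sxx - Sx * Sx
  covariance <- if (is.finite(det) && det > 0) {
    matrix(c(Sxx, -Sx, -Sx, Sw) / det, 2L, 2L, dimnames = dn)
  } else {
    matrix(NA_real_, 2L, 2L, dimnames = dn)
  }
  converged <- res$convergence == 0L && is.finite(det) && det > 0
  reason <- if (converged) NULL else
    paste0("optim convergence code ", res$convergence,
           if (nzchar(res$message %||% "")) paste0(": ", res$message) else "")
  iters <- unname(res$counts["gradient"])
  if (is.na(iters)) iters <- unname(res$counts["function"])
  .logit_fit(theta, covariance, loglik = -res$value, converged = converged,
             iterations = as.integer(iters), optimizer = method,
             reason = reason)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_design <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (!all(y %in% c(0, 1))) stop("y must be 0/1 membership labels")
  if (any(!is.finite(x))) stop("x must be finite")
  if (all(y == 0) || all(y == 1)) {
    stop("degenerate labels: y must contain at least one 0 and one 1")
  }
  list(x = as.numeric(x), y = as.numeric(y))
}

.logit_fit <- function(theta, covariance, loglik, converged, iterations,
                       optimizer, reason = NULL) {
  names(theta) <- c("theta0", "theta1")
  # divergent estimates or an essentially perfect fit signal complete
  # separation: the Wald test is meaningless there, so flag rather than report
  if (converged && is.finite(theta[2L]) && abs(theta[2L]) > 1e3) {
    converged <- FALSE
    reason <- "apparent complete separation (|theta1| > 1000)"
  } else if (converged && theta[2L] != 0 && is.finite(loglik) &&
             loglik > -1e-6) {
    converged <- FALSE
    reason <- "apparent complete separation (perfect classification)"
  }
  structure(list(theta = theta, covariance = covariance,
                 se = sqrt(diag(covariance)), loglik = loglik,
                 converged = converged, iterations = iterations,
                 optimizer = optimizer, reason = reason),
            class = "logit_fit")
}

#' @export
#' @method print logit_fit
print.logit_fit <- function(x, ...) {
  cat("Logistic membership fit (", x$optimizer, "), ",
      if (x$converged) "converged" else paste0("NOT converged (", x$reason, ")"),
      " in ", x$iterations, " iterations\n", sep = "")
  cat(sprintf("  theta0 = %.6g (se %.3g), theta1 = %.6g (se %.3g)\n",
              x$theta[1], x$se[1], x$theta[2], x$se[2]))
  cat(sprintf("  log-likelihood = %.6g\n", x$loglik))
  invisible(x)
}

#' Wald test of the score coefficient
#'
#' Tests theta1 = 0 with the statistic theta1 / se(theta1). The reference
#' distribution is the standard normal (`"normal_z"`, the conventional Wald
#' reference for binomial GLMs) or, as a compatibility option, a Student t
#' with one degree of freedom (`"t_df1"`).
#'
#' @param fit A converged `logit_fit`.
#' @param df_mode `"normal_z"` or `"t_df1"`.
#' @return List with `statistic` and `p` (two-sided).
#' @export
wald_test <- function(fit, df_mode = c("normal_z", "t_df1")) {
  df_mode <- match.arg(df_mode)
  stopifnot(inherits(fit, "logit_fit"))
  if (!fit$converged) stop("Wald test undefined: fit did not converge")
  se <- fit$se[["theta1"]]
  if (!is.finite(se) || se <= 0) {
    stop("Wald test undefined: standard error of theta1 is ", se)
  }
  stat <- fit$theta[["theta1"]] / se
  p <- if (df_mode == "normal_z") {
    2 * stats::pnorm(-abs(stat))
  } else {
    2 * stats::pt(-abs(stat), df = 1)
  }
  list(statistic = stat, p = p)
}

#' Benjamini–Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values, returned
#' in the input order.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, element-wise >= the input and <= 1.
#' @export
adjust_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1] with no NA")
  }
  stats::p.adjust(pvalues, method = "BH")
}
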