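# ---------------------------------------------------------------------------
# Zero-adjusted Poisson (hurdle) abundance model. The two parts are separable
# maximum-likelihood problems: a binomial model of the zero indicator and a
# zero-truncated Poisson model of the positive counts (fitted by Newton
# scoring; the log link is the canonical link of the truncated family, so the
# log-likelihood is concave).
# ---------------------------------------------------------------------------

log1mexp <- function(a) {
  # log(1 - exp(-a)) for a > 0, numerically stable at both ends
  ifelse(a < log(2), log(-expm1(-a)), log1p(-exp(-a)))
}

#' Zero-adjusted Poisson probability mass function
#'
#' \eqn{P(0) = \pi_0}; for \eqn{k \ge 1},
#' \eqn{P(k) = (1-\pi_0) e^{-\mu}\mu^k / (k! (1 - e^{-\mu}))}
#' (a hurdle: free zero mass plus a zero-truncated Poisson).
#'
#' @param k non-negative integer count(s).
#' @param pi0 zero probability in \[0, 1\].
#' @param mu positive-part Poisson parameter, > 0.
#' @param log if TRUE return log-probabilities.
#' @export
dzap <- function(k, pi0, mu, log = FALSE) {
  if (any(mu <= 0)) stop("mu must be > 0")
  if (any(pi0 < 0 | pi0 > 1)) stop("pi0 must lie in [0, 1]")
  if (any(k < 0) || any(k != floor(k))) stop("k must be a non-negative integer")
  lp <- ifelse(k == 0, base::log(pi0),
               base::log1p(-pi0) + stats::dpois(k, mu, log = TRUE) - log1mexp(mu))
  if (log) lp else exp(lp)
}

#' Sample from a zero-adjusted Poisson
#'
#' Exact inverse-CDF sampling of the truncated part, so the marginal law is
#' exactly [dzap()].
#'
#' @param n number of draws.
#' @param pi0,mu parameters, recycled to length n.
#' @export
rzap <- function(n, pi0, mu) {
  pi0 <- rep_len(pi0, n); mu <- rep_len(mu, n)
  if (any(mu <= 0)) stop("mu must be > 0")
  zero <- stats::runif(n) < pi0
  p0 <- exp(-mu)
  k <- stats::qpois(p0 + stats::runif(n) * (1 - p0), mu)
  k <- pmax(k, 1L)  # guard against floating roundoff at the boundary
  ifelse(zero, 0L, k)
}

zap_basis <- function(env_pcs, df, boundary = NULL) {
  if (is.null(env_pcs)) return(NULL)
  x <- as.matrix(env_pcs)
  lapply(seq_len(ncol(x)), function(j) {
    if (is.null(boundary)) splines::ns(x[, j], df = df)
    else splines::ns(x[, j], df = df, knots = boundary[[j]]$knots,
                     Boundary.knots = boundary[[j]]$Boundary.knots)
  })
}

zap_design <- function(env_pcs, basis) {
  n <- if (is.null(env_pcs)) NA else nrow(as.matrix(env_pcs))
  if (is.null(basis)) return(matrix(1, nrow = n, ncol = 1))
  x <- as.matrix(env_pcs)
  mats <- lapply(seq_along(basis), function(j)
    stats::predict(basis[[j]], x[, j]))
  cbind(1, do.call(cbind, mats))
}

# zero-truncated Poisson regression, canonical log link, Newton scoring
fit_truncpois <- function(y, X, tol = 1e-10, max_iter = 100) {
  stopifnot(all(y >= 1))
  beta <- c(base::log(mean(y)), rep(0, ncol(X) - 1))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    eta <- pmin(eta, 30)
    mu <- exp(eta)
    m <- mu / (1 - exp(-mu))            # truncated mean
    w <- pmax(m * (1 + mu - m), 1e-10)  # truncated variance = d m / d eta
    z <- eta + (y - m) / w
    fit <- stats::lm.wfit(X, z, w)
    new_beta <- fit$coefficients
    if (any(!is.finite(new_beta))) stop("truncated-Poisson fit diverged")
    delta <- max(abs(new_beta - beta))
    beta <- new_beta
    if (delta < tol) break
  }
  eta <- pmin(drop(X %*% beta), 30)
  mu <- exp(eta)
  ll <- sum(y * eta - mu - lfactorial(y) - log1mexp(mu))
  list(coefficients = beta, loglik = ll, iterations = it, converged = delta < tol)
}

#' Fit a zero-adjusted Poisson abundance model
#'
#' Hurdle maximum likelihood in two separable parts: logistic regression of
#' the zero indicator and zero-truncated Poisson regression of the positive
#' counts, each over natural-spline terms of the environmental principal
#' components (intercept-only when \code{env_pcs} is NULL). For the
#' intercept-only model the fitted \eqn{\pi_0} is exactly the empirical zero
#' fraction and the positive-part \eqn{\mu} solves
#' \eqn{\mu/(1-e^{-\mu}) = } mean of the positive counts.
#'
#' @param counts non-negative integer plot counts.
#' @param env_pcs optional matrix/data.frame of environmental PCs.
#' @param df spline degrees of freedom per component.
#' @return object of class \code{zap_model} with a [predict][predict.zap_model]
#'   method returning \code{pi0} and \code{mu} per plot.
#' @export
fit_zap <- function(counts, env_pcs = NULL, df = 4) {
  y <- as.numeric(counts)
  if (any(y < 0) || any(y != floor(y))) stop("counts must be non-negative integers")
  if (all(y == 0))
    stop("all counts are zero: the positive part of the hurdle is undefined")
  basis <- zap_basis(env_pcs, df)
  X <- if (is.null(env_pcs)) matrix(1, length(y), 1)
       else zap_design(env_pcs, basis)
  zero_fit <- stats::glm.fit(X, as.numeric(y == 0), family = stats::binomial())
  pos <- y > 0
  pos_fit <- fit_truncpois(y[pos], X[pos, , drop = FALSE])
  ll_zero <- sum(stats::dbinom(as.numeric(y == 0), 1,
                               pmin(pmax(zero_fit$fitted.values, 1e-12), 1 - 1e-12),
                               log = TRUE))
  structure(list(zero_coef = zero_fit$coefficients,
                 pos_coef = pos_fit$coefficients,
                 basis = basis, df = df,
                 loglik_zero = ll_zero, loglik_pos = pos_fit$loglik,
                 loglik = ll_zero + pos_fit$loglik,
                 converged = pos_fit$converged,
                 n = length(y)),
            class = "zap_model")
}

#' Predict hurdle parameters for new plots
#'
#' @param object a \code{zap_model}.
#' @param env_pcs matrix/data.frame of environmental PCs (NULL for
#'   intercept-only models).
#' @param ... unused.
#' @return data.frame with columns \code{pi0} and \code{mu}.
#' @export
predict.zap_model <- function(object, env_pcs = NULL, ...) {
  X <- if (is.null(object$basis)) {
    n <- if (is.null(env_pcs)) 1 else nrow(as.matrix(env_pcs))
    matrix(1, n, 1)
  } else zap_design(env_pcs, object$basis)
  data.frame(pi0 = stats::plogis(drop(X %*% object$zero_coef)),
             mu = exp(pmin(drop(X %*% object$pos_coef), 30)))
}

#' Log-likelihood of a ZAP fit
#'
#' The hurdle factorizes, so the total equals the zero-part plus the
#' positive-part log-likelihoods.
#'
#' @param object a \code{zap_model}.
#' @param ... unused.
#' @export
logLik.zap_model <- function(object, ...) {
  structure(object$loglik, df = length(object$zero_coef) + length(object$pos_coef),
            class = "logLik")
}
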