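# Beta regression for proportion outcomes (logit mean link, common
# precision), used to compare microhomology-bin shares between groups.

#' Fit a two-group beta regression
#'
#' Maximum-likelihood fit of `y ~ Beta(mu * phi, (1 - mu) * phi)` with
#' `logit(mu) = b0 + b1 * group` and a common precision `phi`, by BFGS with
#' analytic gradients from logistic-moment starting values. Inference on the
#' group effect is a Wald z test. Proportions exactly at 0 or 1 are first
#' shrunk by the usual boundary transform `y' = (y (n - 1) + 0.5) / n`.
#'
#' @param y per-sample proportions in `[0, 1]`.
#' @param group binary group labels (logical, 0/1, or two-level factor).
#' @param max_iter maximum BFGS iterations (default 200).
#' @param grad_tol convergence criterion on the gradient norm (default 1e-6).
#' @return list of class `beta_regression_fit`: `coefficients` (intercept,
#'   group; logit scale), `phi`, `se`, `z`, `p_two_sided`, `log_likelihood`,
#'   `mu_hat` (fitted group means), `converged`.
#' @export
beta_regression_fit <- function(y, group, max_iter = 200, grad_tol = 1e-6) {
  g <- if (is.factor(group)) as.integer(group) - 1L else as.integer(as.logical(group))
  stopifnot(length(y) == length(g), all(y >= 0), all(y <= 1))
  if (length(y) < 4 || length(unique(g)) < 2) {
    stop("need n >= 4 with both groups represented")
  }
  n <- length(y)
  if (any(y <= 0 | y >= 1)) {
    y <- (y * (n - 1) + 0.5) / n
  }

  negll <- function(theta) {
    mu <- plogis(theta[1] + theta[2] * g)
    phi <- exp(theta[3])
    -sum(lgamma(phi) - lgamma(mu * phi) - lgamma((1 - mu) * phi) +
           (mu * phi - 1) * log(y) + ((1 - mu) * phi - 1) * log(1 - y))
  }
  neggr <- function(theta) {
    mu <- plogis(theta[1] + theta[2] * g)
    phi <- exp(theta[3])
    ystar <- log(y) - log(1 - y)
    mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
    dmu <- phi * (ystar - mustar) * mu * (1 - mu)
    dphi <- sum(digamma(phi) - mu * digamma(mu * phi) -
                  (1 - mu) * digamma((1 - mu) * phi) +
                  mu * log(y) + (1 - mu) * log(1 - y)) * phi
    -c(sum(dmu), sum(dmu * g), dphi)
  }

  # logistic-moment starting values
  m0 <- mean(y[g == 0]); m1 <- mean(y[g == 1])
  v <- var(y)
  mbar <- mean(y)
  phi0 <- max(mbar * (1 - mbar) / max(v, 1e-6) - 1, 1)
  start <- c(qlogis(m0), qlogis(m1) - qlogis(m0), log(phi0))

  fit <- optim(start, negll, neggr, method = "BFGS",
               control = list(maxit = max_iter), hessian = TRUE)
  # Newton polish to drive the gradient norm below tolerance
  par <- fit$par
  hess <- fit$hessian
  for (it in seq_len(20)) {
    gr <- neggr(par)
    if (sqrt(sum(gr^2)) < grad_tol) break
    hess <- stats::optimHess(par, negll, neggr)
    step <- tryCatch(solve(hess, gr), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    cand <- par - step
    if (!is.finite(negll(cand)) || negll(cand) > negll(par) + 1e-8) break
    par <- cand
  }
  gnorm <- sqrt(sum(neggr(par)^2))
  fit$par <- par
  fit$value <- negll(par)
  fit$hessian <- stats::optimHess(par, negll, neggr)
  converged <- gnorm < grad_tol
  if (!converged && fit$convergence != 0) {
    stop("beta regression did not converge (gradient norm ",
         format(gnorm), ", optim code ", fit$convergence, ")")
  }
  vc <- tryCatch(solve(fit$hessian), error = function(e) {
    matrix(NA_real_, 3, 3)
  })
  se <- sqrt(pmax(diag(vc), 0))
  z <- fit$par[1:2] / se[1:2]
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(
    coefficients = setNames(fit$par[1:2], c("intercept", "group")),
    phi = exp(fit$par[3]),
    se = setNames(se[1:2], c("intercept", "group")),
    z = setNames(z, c("intercept", "group")),
    p_two_sided = unname(p[2]),
    log_likelihood = -fit$value,
    mu_hat = c(group0 = plogis(fit$par[1]),
               group1 = plogis(fit$par[1] + fit$par[2])),
    converged = converged
  ), class = "beta_regression_fit")
}
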