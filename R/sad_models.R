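rad_models <- c("brokenstick", "preemption", "lognormal", "zipf", "mandelbrot")
rad_npar <- c(brokenstick = 0L, preemption = 1L, lognormal = 2L,
              zipf = 2L, mandelbrot = 3L, zsm = 2L)

#' Expected rank abundances under a niche model
#'
#' Evaluates the expected abundance at ranks 1..S for the five classic
#' rank-abundance-distribution (RAD) forms:
#' \describe{
#'   \item{brokenstick}{`(J/S) * sum_{k=r..S} 1/k` (no free parameters).}
#'   \item{preemption}{`J * alpha (1-alpha)^(r-1) / (1 - (1-alpha)^S)`,
#'     geometric niche preemption normalized over the S observed ranks.}
#'   \item{lognormal}{`exp(mu + sigma * qnorm((S - r + 0.5)/S))`, midpoint
#'     plotting positions mapping rank to a normal quantile.}
#'   \item{zipf}{`J * p1 * r^gamma`.}
#'   \item{mandelbrot}{`J * c * (r + beta)^gamma` (Zipf-Mandelbrot; reduces
#'     to zipf at `beta = 0`, `c = p1`).}
#' }
#'
#' @param model One of `"brokenstick"`, `"preemption"`, `"lognormal"`,
#'   `"zipf"`, `"mandelbrot"`.
#' @param params Named list/vector of the model's parameters (none for
#'   brokenstick; `alpha`; `mu`,`sigma`; `p1`,`gamma`; `c`,`gamma`,`beta`).
#' @param S Number of ranks (species).
#' @param J Total abundance scale.
#' @return Numeric vector of length `S`, all entries positive.
#' @export
expected_abundance <- function(model, params = list(), S, J) {
  model <- match.arg(model, rad_models)
  if (S < 1L) abort("S must be >= 1")
  p <- as.list(params)
  r <- seq_len(S)
  lambda <- switch(model,
    brokenstick = (J / S) * rev(cumsum(1 / rev(r))),
    preemption = {
      a <- p$alpha
      if (is.null(a) || a <= 0 || a >= 1) abort("preemption needs alpha in (0,1)")
      J * a * (1 - a)^(r - 1) / (1 - (1 - a)^S)
    },
    lognormal = {
      if (is.null(p$mu) || is.null(p$sigma) || p$sigma <= 0)
        abort("lognormal needs mu and sigma > 0")
      exp(p$mu + p$sigma * qnorm((S - r + 0.5) / S))
    },
    zipf = {
      if (is.null(p$p1) || is.null(p$gamma) || p$p1 <= 0 || p$p1 > 1 || p$gamma >= 0)
        abort("zipf needs p1 in (0,1] and gamma < 0")
      J * p$p1 * r^p$gamma
    },
    mandelbrot = {
      if (is.null(p$c) || is.null(p$gamma) || is.null(p$beta) ||
          p$c <= 0 || p$gamma >= 0 || p$beta <= -1)
        abort("mandelbrot needs c > 0, gamma < 0, beta > -1")
      J * p$c * (r + p$beta)^p$gamma
    })
  if (any(!is.finite(lambda)) || any(lambda <= 0)) {
    abort("expected abundances must be positive and finite")
  }
  lambda
}

# Poisson log-likelihood of observed abundances a around expectations lambda
poisson_loglik <- function(a, lambda) {
  sum(a * log(lambda) - lambda - lgamma(a + 1))
}

# validate + sort a rank-abundance vector (descending; ties keep input order)
as_rank_abundance <- function(abund) {
  abund <- as.numeric(abund[abund > 0])
  if (length(abund) == 0L) abort("rank abundance vector has no positive entries")
  if (any(abund != floor(abund))) abort("abundances must be integers")
  sort(abund, decreasing = TRUE)
}

#' Fit a niche rank-abundance model by maximum likelihood
#'
#' Maximizes the Poisson log-likelihood
#' `sum_r [a_r log(lambda_r) - lambda_r - log(a_r!)]` of the observed ranked
#' abundances around the model's expected abundances ([expected_abundance()]).
#' The broken-stick model has no free parameters; one-parameter models use
#' golden-section search on a transformed scale and multi-parameter models
#' use Nelder-Mead from a small deterministic grid of starts (including
#' data-driven starts; the Zipf-Mandelbrot starts include the fitted Zipf
#' solution, so its likelihood can never fall below Zipf's).
#'
#' @param abund Positive integer abundances (sorted internally).
#' @param model One of the five niche models (see [expected_abundance()]).
#' @return A `rad_fit` object: model, parameter estimates, `log_lik`,
#'   `npar`, `aic = -2 log_lik + 2 npar`, and a convergence flag.
#' @export
fit_rad_model <- function(abund, model) {
  model <- match.arg(model, rad_models)
  a <- as_rank_abundance(abund)
  S <- length(a); J <- sum(a)
  npar <- rad_npar[[model]]
  if (S < npar + 1L) abort(sprintf("need at least %d species to fit %s", npar + 1L, model))

  make_fit <- function(par, log_lik, converged) {
    structure(list(model = model, par = par, log_lik = log_lik, npar = npar,
                   aic = -2 * log_lik + 2 * npar, converged = converged,
                   S = S, J = J, abund = a),
              class = "rad_fit")
  }

  if (model == "brokenstick") {
    lam <- expected_abundance("brokenstick", S = S, J = J)
    return(make_fit(numeric(0), poisson_loglik(a, lam), TRUE))
  }

  obj <- function(theta) {
    par <- rad_untransform(model, theta)
    lam <- try(expected_abundance(model, par, S, J), silent = TRUE)
    if (inherits(lam, "try-error")) return(1e10)
    ll <- poisson_loglik(a, lam)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  if (model == "preemption") {
    opt <- stats::optimize(function(t) obj(t), interval = c(-12, 12), tol = 1e-10)
    par <- rad_untransform(model, opt$minimum)
    return(make_fit(par, -opt$objective, TRUE))
  }

  best <- NULL
  for (start in rad_starts(model, a, S, J)) {
    o <- optim(start, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
    if (is.null(best) || o$value < best$value) best <- o
  }
  par <- rad_untransform(model, best$par)
  make_fit(par, -best$value, best$convergence == 0)
}

# unconstrained <-> natural parameter transforms per model
rad_untransform <- function(model, theta) {
  switch(model,
    preemption = c(alpha = plogis(theta[1])),
    lognormal = c(mu = theta[1], sigma = exp(theta[2])),
    zipf = c(p1 = plogis(theta[1]), gamma = -exp(theta[2])),
    mandelbrot = c(c = exp(theta[1]), gamma = -exp(theta[2]),
                   beta = expm1(theta[3])))
}

rad_starts <- function(model, a, S, J) {
  r <- seq_along(a)
  # data-driven slope/intercept on the log-log rank plot
  zfit <- coef(lm(log(a) ~ log(r)))
  gam <- min(zfit[2], -1e-3)
  p1 <- min(max(exp(zfit[1]) / J, 1e-8), 1 - 1e-8)
  switch(model,
    lognormal = {
      mu <- mean(log(a)); s <- max(sd(log(a)), 0.1)
      list(c(mu, log(s)), c(mu, log(2 * s)), c(mu - 1, log(s)),
           c(mu + 1, log(s / 2)), c(0, 0))
    },
    zipf = {
      list(c(qlogis(p1), log(-gam)), c(qlogis(p1), 0), c(0, 0),
           c(-2, log(0.5)), c(2, log(2)))
    },
    mandelbrot = {
      zf <- fit_rad_model(a, "zipf")
      zc <- log(zf$par[["p1"]]); zg <- log(-zf$par[["gamma"]])
      list(c(zc, zg, 0), c(zc, zg, log1p(1)), c(zc, zg, log1p(5)),
           c(zc - 1, zg + 0.5, log1p(0.5)), c(0, 0, 0))
    })
}

#' @method print rad_fit
#' @export
print.rad_fit <- function(x, ...) {
  cat(sprintf("<rad_fit> %s: logLik %.3f, npar %d, AIC %.3f%s\n", x$model,
              x$log_lik, x$npar, x$aic,
              if (x$converged) "" else " (not converged)"))
  if (length(x$par)) {
    cat("  ", paste(sprintf("%s = %.5g", names(x$par), x$par), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname fit_rad_model
#' @param x A `rad_fit` object.
#' @param ... Unused.
#' @method tidy rad_fit
#' @export
tidy.rad_fit <- function(x, ...) {
  if (!length(x$par)) {
    return(tibble::tibble(model = character(), term = character(),
                          estimate = numeric()))
  }
  tibble::tibble(model = x$model, term = names(x$par),
                 estimate = unname(x$par))
}

#' @rdname fit_rad_model
#' @method glance rad_fit
#' @export
glance.rad_fit <- function(x, ...) {
  tibble::tibble(model = x$model, log_lik = x$log_lik, npar = x$npar,
                 aic = x$aic, converged = x$converged, s = x$S, j = x$J)
}

#' Akaike weights from a set of AIC values
#'
#' `w_i = exp(-0.5 dAIC_i) / sum_k exp(-0.5 dAIC_k)` with
#' `dAIC_i = AIC_i - min(AIC)`: the weight of evidence in favor of each
#' model. Non-finite AICs (failed fits) receive weight 0; names are
#' preserved. Weights are invariant to adding a constant to every AIC.
#'
#' @param aic Numeric vector of AIC values, at least one finite.
#' @return Weights summing to 1, same length and names as `aic`.
#' @export
akaike_weights <- function(aic) {
  ok <- is.finite(aic)
  if (!any(ok)) abort("all AIC values are non-finite")
  w <- rep(0, length(aic))
  d <- aic[ok] - min(aic[ok])
  ew <- exp(-0.5 * d)
  w[ok] <- ew / sum(ew)
  names(w) <- names(aic)
  w
}
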