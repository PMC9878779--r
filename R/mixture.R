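## Exact Ruben expansion of a positively weighted sum of 1-df chi-squares as
## an infinite mixture of central chi-squares with scale beta = min(lambda):
##   P(Q <= q) = sum_r a_r P(chisq_{k+2r} <= q / beta),  a_r >= 0, sum a_r = 1.
## Truncation error is bounded by the unaccumulated mixing mass, which gives a
## certified absolute accuracy for both tails. Convergence slows as
## max(lambda)/min(lambda) grows; callers fall back to moment matching when
## the series does not reach `acc` within `max_terms`.
.ruben_series <- function(lambda, acc = 1e-9, max_terms = 8000L) {
  k <- length(lambda)
  beta <- min(lambda)
  ratio <- 1 - beta / lambda                # in [0, 1)
  a <- numeric(max_terms + 1L)
  g <- numeric(max_terms)
  a[1L] <- prod(sqrt(beta / lambda))
  pr <- ratio
  total <- a[1L]
  r <- 0L
  while (total < 1 - acc && r < max_terms) {
    r <- r + 1L
    g[r] <- 0.5 * sum(pr)
    pr <- pr * ratio
    a[r + 1L] <- sum(g[r:1L] * a[1L:r]) / r
    total <- total + a[r + 1L]
  }
  list(beta = beta, a = a[1L:(r + 1L)], k = k,
       remainder = max(1 - total, 0), converged = total >= 1 - acc)
}

## upper-tail probability from a Ruben series; vectorized over q
.ruben_survival <- function(q, series) {
  df <- series$k + 2 * (seq_along(series$a) - 1L)
  vapply(q, function(qi) {
    if (qi <= 0) return(1)
    s <- sum(series$a * stats::pchisq(qi / series$beta, df = df,
                                      lower.tail = FALSE))
    min(max(s, 0), 1)
  }, numeric(1L))
}

.ruben_cdf <- function(q, series) 1 - .ruben_survival(q, series)

## Liu-Tang-Zhang moment-matching survival function (non-central chi-square
## with matched skewness/kurtosis); used as flagged fallback only.
.liu_survival <- function(q, lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    aa <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * aa^3 - aa^2
    l <- aa^2 - 2 * delta
  } else {
    delta <- 0
    l <- 1 / s2
  }
  muX <- l + delta
  sigmaX <- sqrt(2 * (l + 2 * delta))
  tstar <- (q - c1) / sqrt(2 * c2)
  stats::pchisq(tstar * sigmaX + muX, df = l, ncp = delta,
                lower.tail = FALSE)
}

## Lugannani-Rice saddlepoint survival approximation for sum(lambda*chisq_1):
## cumulant generating function K(z) = -0.5 sum log(1 - 2 z lambda).
## Monotone-accurate in both tails (relative error); undefined exactly at the
## mean, where callers switch to moment matching. Vectorized over q.
.spa_survival <- function(q, lambda) {
  zmax <- 1 / (2 * max(lambda))
  Kp <- function(z) sum(lambda / (1 - 2 * z * lambda))
  vapply(q, function(qi) {
    if (qi <= 0) return(1)
    mu <- sum(lambda)
    if (abs(qi - mu) < 1e-8 * mu) return(NA_real_)   # w ~ 0: caller falls back
    ## solve K'(z) = q; K' is increasing, so bisection is safe
    lo <- -1e3 / mu
    hi <- zmax * (1 - 1e-12)
    while (Kp(lo) > qi) lo <- lo * 2
    zh <- tryCatch(stats::uniroot(function(z) Kp(z) - qi, lower = lo,
                                  upper = hi, tol = 1e-14)$root,
                   error = function(e) NA_real_)
    if (!is.finite(zh)) return(NA_real_)
    K0 <- -0.5 * sum(log1p(-2 * zh * lambda))
    K2 <- 2 * sum(lambda^2 / (1 - 2 * zh * lambda)^2)
    w <- sign(zh) * sqrt(max(2 * (zh * qi - K0), 0))
    v <- zh * sqrt(K2)
    if (abs(w) < 1e-4 || abs(v) < 1e-12) return(NA_real_)
    p <- stats::pnorm(w + log(v / w) / w, lower.tail = FALSE)
    min(max(p, 0), 1)
  }, numeric(1L))
}

#' Tail probability of a weighted sum of 1-df chi-squares
#'
#' Computes \eqn{P(\sum_k \lambda_k \chi^2_1 \ge q)}, the reference
#' distribution of variance-component score statistics, by exact numerical
#' inversion (Ruben's central chi-square expansion, evaluated to the requested
#' absolute accuracy with a certified truncation bound). When the eigenvalue
#' spread makes the series impractically long, a Lugannani-Rice saddlepoint
#' approximation of the survival function takes over (relative-accurate in
#' both tails), and only if that too is unavailable (statistic at the
#' distribution mean, degenerate inputs) a Liu-type moment-matching
#' approximation is used. The method actually applied is reported in the
#' `"method"` attribute (`"ruben"`, `"spa"`, `"liu"`, `"degenerate"`).
#'
#' Mixture coefficients more negative than `-tol * max(lambda)` are rejected;
#' negatives within tolerance are clipped to zero. If all coefficients are
#' zero the statistic is degenerate at 0 and the tail probability is 1.
#'
#' @param q observed statistic, `>= 0`.
#' @param lambda mixture coefficients (eigenvalues of the projected weighted
#'   kernel).
#' @param acc target absolute accuracy of the inversion (default 1e-9).
#' @param max_terms series-length cap before falling back to moment matching.
#' @param tol relative clipping threshold for small negative eigenvalues.
#' @return the tail probability, with attribute `method` (`"ruben"`,
#'   `"liu"`, or `"degenerate"`).
#' @export
mixture_chisq_pvalue <- function(q, lambda, acc = 1e-9, max_terms = 2000L,
                                 tol = 1e-10) {
  stopifnot(length(q) == 1L, is.finite(q), q >= 0)
  lambda <- as.numeric(lambda)
  if (length(lambda)) {
    thr <- tol * max(abs(lambda))
    if (any(lambda < -thr))
      .stopf("mixture coefficients must be non-negative (min = %.3g)",
             min(lambda))
    lambda <- lambda[lambda > thr]
  }
  sv <- .mix_survival_fun(lambda, acc = acc, max_terms = max_terms)
  structure(sv$surv(q), method = sv$method)
}

## Build a survival-function closure for one eigenvalue set, choosing the
## numerical route once: exact Ruben series when it converges within
## max_terms; otherwise saddlepoint with per-point Liu fallback near the mean.
.mix_survival_fun <- function(lambda, acc = 1e-9, max_terms = 2000L) {
  lambda <- lambda[lambda > 0]
  if (length(lambda) == 0L)
    return(list(surv = function(q) rep(1, length(q)), mu = 0, sd = 0,
                method = "degenerate"))
  mu <- sum(lambda); sd <- sqrt(2 * sum(lambda^2))
  if (length(lambda) == 1L) {
    lam <- lambda
    return(list(surv = function(q) stats::pchisq(q / lam, df = 1,
                                                 lower.tail = FALSE),
                mu = mu, sd = sd, method = "ruben"))
  }
  ## only attempt the series when the spread makes convergence plausible
  if (max(lambda) / min(lambda) < max_terms / 25) {
    ser <- .ruben_series(lambda, acc = acc, max_terms = max_terms)
    if (ser$converged)
      return(list(surv = function(q) .ruben_survival(q, ser),
                  mu = mu, sd = sd, method = "ruben"))
  }
  list(surv = function(q) {
    p <- .spa_survival(q, lambda)
    bad <- !is.finite(p)
    if (any(bad))
      p[bad] <- pmin(pmax(.liu_survival(q[bad], lambda), 0), 1)
    p
  }, mu = mu, sd = sd, method = "spa")
}

## quantile q such that survival(q) = prob, by bisection-safe root finding on
## a prepared survival closure (decreasing in q)
.mixture_quantile <- function(surv_fun, prob, mu, sd) {
  hi <- max(mu + 10 * sd, 1)
  it <- 0L
  while (surv_fun(hi) > prob && it < 60L) {
    hi <- hi * 2
    it <- it + 1L
  }
  stats::uniroot(function(x) surv_fun(x) - prob, lower = 0, upper = hi,
                 tol = 1e-10 * max(hi, 1))$root
}
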