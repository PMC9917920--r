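#' Truncated-normal moments, moment matching, and sampling
#'
#' Age distributions are modelled as normal distributions truncated to the
#' study age window (default 18--74 years). Published population tables print
#' the mean and SD of the *truncated* variable, so the underlying normal
#' parameters (mu, sigma) must be solved so that the truncated moments hit the
#' targets. All tail quantities are computed in log space so that strongly
#' tilted fits (mu far outside the window, large sigma) remain accurate.
#'
#' @name truncnorm-tools
NULL

# log(Phi(b) - Phi(a)), stable in either tail (reflect so both args <= 0)
tn_log_mass <- function(a, b) {
  if (a > 0) {
    tmp <- a
    a <- -b
    b <- -tmp
  }
  lpa <- stats::pnorm(a, log.p = TRUE)
  lpb <- stats::pnorm(b, log.p = TRUE)
  lpb + log1p(-exp(lpa - lpb))
}

#' Mean and SD of a normal(mu, sigma) truncated to `[lo, hi]`
#'
#' Closed-form moments via normalized hazard ratios phi(.)/Z computed in log
#' space.
#'
#' @param mu,sigma parameters of the untruncated normal (sigma > 0).
#' @param lo,hi truncation bounds, `lo < hi`.
#' @return named numeric vector with elements `mean` and `sd`.
#' @export
truncnorm_moments <- function(mu, sigma, lo, hi) {
  stopifnot(sigma > 0, lo < hi)
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  logZ <- tn_log_mass(a, b)
  ra <- exp(stats::dnorm(a, log = TRUE) - logZ)
  rb <- exp(stats::dnorm(b, log = TRUE) - logZ)
  m <- mu + sigma * (ra - rb)
  v <- sigma^2 * (1 + a * ra - b * rb - (ra - rb)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# mu that puts the truncated mean at target_mean, for fixed sigma.
# The truncated mean is strictly increasing in mu; the usable mu range scales
# with sigma^2 because the effective exponential tilt is (mu - x) / sigma^2.
tn_mu_for_mean <- function(target_mean, sigma, lo, hi) {
  f <- function(mu) truncnorm_moments(mu, sigma, lo, hi)[["mean"]] - target_mean
  w <- max(10 * (hi - lo), 0.75 * sigma^2)
  stats::uniroot(f, c(lo - w, hi + w), tol = 1e-12)$root
}

# Largest sigma considered before the family is numerically indistinguishable
# from its exponential-tilt limit.
tn_sigma_cap <- function(lo, hi) 8 * (hi - lo)

#' Attainable SD supremum of a truncated normal with a given mean
#'
#' For a fixed truncated mean, the truncated SD increases with sigma and
#' approaches a finite supremum as sigma grows (the limit distribution is an
#' exponential tilt on `[lo, hi]`; the global supremum over all means is the
#' uniform SD, `(hi - lo)/sqrt(12)`). Published mean/SD pairs can exceed this
#' bound, in which case no truncated normal reproduces both moments.
#'
#' @inheritParams truncnorm_moments
#' @param target_mean required truncated mean, strictly inside `(lo, hi)`.
#' @return the largest truncated SD attainable (at `sigma = 8 * (hi - lo)`,
#'   within ~0.03 of the true supremum for the default age window).
#' @export
truncnorm_max_sd <- function(target_mean, lo, hi) {
  s <- tn_sigma_cap(lo, hi)
  mu <- tn_mu_for_mean(target_mean, s, lo, hi)
  truncnorm_moments(mu, s, lo, hi)[["sd"]]
}

#' Solve truncated-normal parameters matching target moments
#'
#' Finds `(mu, sigma)` such that the normal truncated to `[lo, hi]` has the
#' requested mean and SD. The solve is nested root finding: for each sigma the
#' mean is matched exactly through mu (monotone in mu), and sigma is then
#' adjusted until the SD matches (monotone in sigma along the mean-matched
#' family). Convergence tolerance is 1e-8 on both moments.
#'
#' Not every printed mean/SD pair is attainable: given the mean, the SD is
#' bounded above by [truncnorm_max_sd()]. `on_infeasible` controls what
#' happens then: `"error"` signals an infeasibility error naming the violated
#' bound; `"nearest"` returns the boundary fit (mean matched exactly, SD at
#' its attainable maximum) with a warning.
#'
#' @param target_mean,target_sd required truncated moments (years).
#' @param lo,hi truncation bounds (years), `lo < target_mean < hi`.
#' @param on_infeasible `"error"` or `"nearest"` (see Details).
#' @return list with `mu`, `sigma`, `achieved` (named mean/sd vector), and
#'   `clamped` (logical: TRUE when the SD was clamped to the boundary).
#' @examples
#' fit <- fit_truncnorm_moments(52.3, 15.2, 18, 74)
#' truncnorm_moments(fit$mu, fit$sigma, 18, 74)
#' @export
fit_truncnorm_moments <- function(target_mean, target_sd, lo, hi,
                                  on_infeasible = c("error", "nearest")) {
  on_infeasible <- match.arg(on_infeasible)
  if (!(lo < target_mean && target_mean < hi)) {
    stop(sprintf(
      "infeasible target: mean %.6g outside the open interval (%g, %g)",
      target_mean, lo, hi
    ), call. = FALSE)
  }
  if (target_sd <= 0) {
    stop("infeasible target: target SD must be > 0", call. = FALSE)
  }
  sd_cap <- truncnorm_max_sd(target_mean, lo, hi)
  clamped <- FALSE
  if (target_sd > sd_cap) {
    if (on_infeasible == "error") {
      stop(sprintf(paste0(
        "infeasible target: SD %.6g exceeds the maximum SD %.6g attainable ",
        "by a truncated normal on [%g, %g] with mean %.6g"
      ), target_sd, sd_cap, lo, hi, target_mean), call. = FALSE)
    }
    warning(sprintf(paste0(
      "target SD %.3f not attainable with mean %.3f on [%g, %g]; ",
      "clamped to %.3f (mean preserved exactly)"
    ), target_sd, target_mean, lo, hi, sd_cap), call. = FALSE)
    clamped <- TRUE
  }
  s_hi <- tn_sigma_cap(lo, hi)
  if (clamped) {
    sigma <- s_hi
  } else {
    g <- function(sigma) {
      mu <- tn_mu_for_mean(target_mean, sigma, lo, hi)
      truncnorm_moments(mu, sigma, lo, hi)[["sd"]] - target_sd
    }
    # truncated sd < sigma always, so sigma = target_sd gives g < 0
    sigma <- stats::uniroot(g, c(target_sd, s_hi), tol = 1e-10)$root
  }
  mu <- tn_mu_for_mean(target_mean, sigma, lo, hi)
  achieved <- truncnorm_moments(mu, sigma, lo, hi)
  if (!clamped &&
      (abs(achieved[["mean"]] - target_mean) > 1e-8 ||
       abs(achieved[["sd"]] - target_sd) > 1e-8)) {
    stop("moment solve failed to converge to 1e-8", call. = FALSE)
  }
  list(mu = mu, sigma = sigma, achieved = achieved, clamped = clamped)
}

#' Sample from a truncated normal by inversion
#'
#' Inverse-CDF sampling: uniforms are mapped through the normal quantile
#' function restricted to the truncation mass, with the mass accumulated in
#' log space so extreme tilts keep full accuracy.
#'
#' @param n number of draws.
#' @inheritParams truncnorm_moments
#' @return numeric vector of length `n` in `[lo, hi]`.
#' @export
rtruncnorm <- function(n, mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  u <- stats::runif(n)
  logZ <- tn_log_mass(a, b)
  lse2 <- function(x, y) {
    m <- pmax(x, y)
    m + log(exp(x - m) + exp(y - m))
  }
  if (a <= 0) {
    # p = Phi(a) + u * Z, accumulated in log space
    lpa <- stats::pnorm(a, log.p = TRUE)
    q <- stats::qnorm(lse2(lpa, logZ + log(u)), log.p = TRUE)
  } else {
    # reflect to keep the accumulated tail on the small side
    lpb <- stats::pnorm(-b, log.p = TRUE)
    q <- -stats::qnorm(lse2(lpb, logZ + log1p(-u)), log.p = TRUE)
  }
  pmin(pmax(mu + sigma * q, lo), hi)
}
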