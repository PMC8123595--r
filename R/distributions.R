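#' Fit a truncated-lognormal service-time component through two quantiles
#'
#' Service-time components of the transport chain (clinical time from test
#' ordering to sample dispatch, pneumatic-tube transport, laboratory
#' processing) are summarised in the source material by two printed
#' quantiles and a plausible range. A lognormal distribution is pinned
#' exactly through the two quantile anchors on the untruncated scale and
#' then truncated to \code{[lower, upper]} by rejection when sampled;
#' right-skew in the printed percentile gaps motivates the lognormal family.
#'
#' With anchors \eqn{(p_1, v_1)} and \eqn{(p_2, v_2)} the two-quantile
#' equations \eqn{\log v_i = \mu + \sigma z_{p_i}} have the closed-form
#' solution \eqn{\sigma = (\log v_2 - \log v_1) / (z_{p_2} - z_{p_1})},
#' \eqn{\mu = \log v_1 - \sigma z_{p_1}}. Equal anchor values force
#' \eqn{\sigma = 0}: a point mass at the anchor.
#'
#' @param anchor_lo,anchor_hi numeric length-2 vectors \code{c(probability,
#'   minutes)}; probabilities must be strictly increasing and minutes
#'   positive and non-decreasing.
#' @param lower,upper truncation bounds in minutes; \code{lower >= 0},
#'   \code{upper > lower}, and the anchors must lie inside the bounds.
#' @return A \code{dist_spec} object: list with \code{mu}, \code{sigma},
#'   \code{lower}, \code{upper} and the \code{anchors} matrix.
#' @examples
#' lab <- fit_truncated_lognormal(c(0.50, 15), c(0.95, 116), 0, 125)
#' dist_quantile(lab, 0.5) # 15, on the untruncated scale
#' @export
fit_truncated_lognormal <- function(anchor_lo, anchor_hi, lower = 0,
                                    upper = Inf) {
  if (!is.numeric(anchor_lo) || length(anchor_lo) != 2L ||
      !is.numeric(anchor_hi) || length(anchor_hi) != 2L) {
    stop_dronelab("anchors must be numeric (probability, minutes) pairs",
                  "dronelab_invalid_anchor")
  }
  p_lo <- anchor_lo[1]; v_lo <- anchor_lo[2]
  p_hi <- anchor_hi[1]; v_hi <- anchor_hi[2]
  if (!(p_lo > 0 && p_hi < 1 && p_lo < p_hi)) {
    stop_dronelab("anchor probabilities must satisfy 0 < p_lo < p_hi < 1",
                  "dronelab_invalid_anchor")
  }
  if (!(v_lo > 0 && v_hi >= v_lo)) {
    stop_dronelab("anchor values must be positive with v_lo <= v_hi",
                  "dronelab_invalid_anchor")
  }
  if (!(lower >= 0 && upper > lower && lower <= v_lo && v_hi <= upper)) {
    stop_dronelab("anchors must lie within [lower, upper], lower >= 0",
                  "dronelab_invalid_anchor")
  }
  z_lo <- stats::qnorm(p_lo)
  z_hi <- stats::qnorm(p_hi)
  sigma <- (log(v_hi) - log(v_lo)) / (z_hi - z_lo)
  mu <- log(v_lo) - sigma * z_lo
  structure(
    list(mu = mu, sigma = sigma, lower = lower, upper = upper,
         anchors = rbind(lo = c(p = p_lo, minutes = v_lo),
                         hi = c(p = p_hi, minutes = v_hi))),
    class = "dist_spec"
  )
}

#' Point-mass component at a fixed time
#'
#' Convenience constructor for a degenerate component (all mass at
#' \code{minutes}), used for switching individual parts of the time chain
#' off or pinning them in what-if runs.
#'
#' @param minutes the fixed component time, minutes >= 0.
#' @return A \code{dist_spec} with \code{sigma = 0}.
#' @export
dist_point_mass <- function(minutes) {
  stopifnot(is_number(minutes), minutes >= 0)
  if (minutes == 0) {
    # log-scale location undefined at 0; represented directly
    return(structure(
      list(mu = -Inf, sigma = 0, lower = 0, upper = Inf,
           anchors = rbind(lo = c(p = 0.5, minutes = 0),
                           hi = c(p = 0.95, minutes = 0))),
      class = "dist_spec"
    ))
  }
  fit_truncated_lognormal(c(0.5, minutes), c(0.95, minutes), 0, Inf)
}

#' @export
print.dist_spec <- function(x, ...) {
  cat("Truncated lognormal service-time component\n")
  cat(sprintf("  mu = %.4f, sigma = %.4f (log-minute scale)\n", x$mu, x$sigma))
  cat(sprintf("  support after truncation: [%g, %g] min\n", x$lower, x$upper))
  cat(sprintf("  anchors: P(T <= %g) = %.2f, P(T <= %g) = %.2f (untruncated)\n",
              x$anchors["lo", "minutes"], x$anchors["lo", "p"],
              x$anchors["hi", "minutes"], x$anchors["hi", "p"]))
  invisible(x)
}

#' Component CDF
#'
#' @param spec a \code{dist_spec}.
#' @param q vector of times in minutes.
#' @param truncated if \code{TRUE} (default) the CDF of the truncated
#'   distribution; otherwise the untruncated lognormal CDF on which the
#'   anchors are defined.
#' @return Probabilities.
#' @export
dist_cdf <- function(spec, q, truncated = TRUE) {
  stopifnot(inherits(spec, "dist_spec"))
  if (spec$sigma == 0) {
    point <- if (is.finite(spec$mu)) exp(spec$mu) else 0
    return(as.numeric(q >= point))
  }
  raw <- stats::plnorm(q, spec$mu, spec$sigma)
  if (!truncated) return(raw)
  f_lo <- stats::plnorm(spec$lower, spec$mu, spec$sigma)
  f_hi <- stats::plnorm(spec$upper, spec$mu, spec$sigma)
  pmin(1, pmax(0, (raw - f_lo) / (f_hi - f_lo)))
}

#' Component quantile function
#'
#' @inheritParams dist_cdf
#' @param p vector of probabilities.
#' @export
dist_quantile <- function(spec, p, truncated = TRUE) {
  stopifnot(inherits(spec, "dist_spec"))
  if (spec$sigma == 0) {
    point <- if (is.finite(spec$mu)) exp(spec$mu) else 0
    return(rep(point, length(p)))
  }
  if (!truncated) return(stats::qlnorm(p, spec$mu, spec$sigma))
  f_lo <- stats::plnorm(spec$lower, spec$mu, spec$sigma)
  f_hi <- stats::plnorm(spec$upper, spec$mu, spec$sigma)
  stats::qlnorm(f_lo + p * (f_hi - f_lo), spec$mu, spec$sigma)
}

#' Draw component times by rejection inside the truncation bounds
#'
#' Lognormal draws outside \code{[lower, upper]} are redrawn until all
#' \code{n} values fall inside the bounds, so the sample follows the
#' truncated distribution exactly.
#'
#' @inheritParams dist_cdf
#' @param n number of draws.
#' @return Numeric vector of \code{n} times in minutes, all inside
#'   \code{[lower, upper]}.
#' @export
dist_draw <- function(spec, n) {
  stopifnot(inherits(spec, "dist_spec"), is.numeric(n), n >= 0)
  n <- as.integer(n)
  if (n == 0L) return(numeric(0))
  if (spec$sigma == 0) {
    point <- if (is.finite(spec$mu)) exp(spec$mu) else 0
    return(rep(point, n))
  }
  mass <- stats::plnorm(spec$upper, spec$mu, spec$sigma) -
    stats::plnorm(spec$lower, spec$mu, spec$sigma)
  if (mass < 1e-10) {
    stop_dronelab("truncation bounds leave (almost) no probability mass",
                  "dronelab_invalid_spec")
  }
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0L) {
    draw <- stats::rlnorm(length(todo), spec$mu, spec$sigma)
    ok <- draw >= spec$lower & draw <= spec$upper
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

#' Mean of a truncated-lognormal component
#'
#' Closed-form mean of the lognormal restricted to \code{[lower, upper]}.
#'
#' @inheritParams dist_cdf
#' @export
dist_mean <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  if (spec$sigma == 0) return(if (is.finite(spec$mu)) exp(spec$mu) else 0)
  mu <- spec$mu; s <- spec$sigma
  a <- if (spec$lower > 0) (log(spec$lower) - mu) / s else -Inf
  b <- if (is.finite(spec$upper)) (log(spec$upper) - mu) / s else Inf
  num <- stats::pnorm(b - s) - stats::pnorm(a - s)
  den <- stats::pnorm(b) - stats::pnorm(a)
  exp(mu + s^2 / 2) * num / den
}

#' Default service-time components of the transport chain
#'
#' The three components, each fitted through its printed quantile anchors
#' and truncated to the printed plausible range:
#' \itemize{
#'   \item \code{clinical}: test ordering to sample dispatch; median 11 min,
#'     95th percentile 75 min, range [0, 180].
#'   \item \code{pts}: pneumatic-tube/porter transport to the drone loading
#'     site; 95th percentile 7 min, range [0, 28]. Only one quantile is
#'     printed for this component; the median anchor is set to 3 min, which
#'     puts the lognormal mean near the printed mean of 3.2 min.
#'   \item \code{lab}: laboratory processing after arrival; median 15 min,
#'     95th percentile 116 min, range [0, 125].
#' }
#'
#' @return Named list of three \code{dist_spec} objects.
#' @export
default_components <- function() {
  list(
    clinical = fit_truncated_lognormal(c(0.50, 11), c(0.95, 75), 0, 180),
    pts      = fit_truncated_lognormal(c(0.50, 3),  c(0.95, 7),  0, 28),
    lab      = fit_truncated_lognormal(c(0.50, 15), c(0.95, 116), 0, 125)
  )
}
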