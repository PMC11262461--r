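#' Tweedie (compound Poisson-Gamma) numerics
#'
#' Density, deviance and random sampling for the Tweedie exponential
#' dispersion family with power parameter `p` in (1, 2): a Poisson number
#' of Gamma jumps, giving a point mass at zero plus a continuous positive
#' component with variance function `V(mu) = mu^p`.
#'
#' @name tweedie-numerics
NULL

check_power <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 1 || p >= 2) {
    abort("`p` must be a single number strictly between 1 and 2.")
  }
  invisible(p)
}

#' Tweedie unit deviance
#'
#' Unit deviance of the Tweedie family with `1 < p < 2`,
#' `d(y, mu) = 2 * (y^(2-p)/((1-p)(2-p)) - y mu^(1-p)/(1-p) + mu^(2-p)/(2-p))`.
#' Non-negative, zero iff `y == mu`. Vectorized over `y` and `mu`.
#'
#' @param y Non-negative observations.
#' @param mu Positive means.
#' @param p Tweedie power in (1, 2).
#' @return Numeric vector of unit deviances.
#' @export
#' @examples
#' tweedie_unit_deviance(3, 3, 1.5)        # 0
#' tweedie_unit_deviance(0, 2, 1.5)        # 4 * sqrt(2)
tweedie_unit_deviance <- function(y, mu, p) {
  check_power(p)
  if (any(y < 0)) abort("`y` must be non-negative.")
  if (any(mu <= 0)) abort("`mu` must be positive.")
  d <- 2 * (y^(2 - p) / ((1 - p) * (2 - p)) -
              y * mu^(1 - p) / (1 - p) +
              mu^(2 - p) / (2 - p))
  pmax(d, 0) # guard tiny negative round-off at y == mu
}

# Compound Poisson-Gamma parameterization for mean mu, dispersion phi, power p:
# N ~ Poisson(lambda), Y | N = n ~ Gamma(shape n * alpha, scale gam), Y = 0 if N = 0
# lambda = mu^(2-p) / (phi (2-p)); alpha = (2-p)/(p-1); gam = phi (p-1) mu^(p-1)
cpg_params <- function(mu, phi, p) {
  list(
    lambda = mu^(2 - p) / (phi * (2 - p)),
    alpha = (2 - p) / (p - 1),
    gam = phi * (p - 1) * mu^(p - 1)
  )
}

#' Tweedie log density
#'
#' Exact log density of the Tweedie compound Poisson-Gamma distribution with
#' `1 < p < 2`. For `y == 0` the point mass `exp(-mu^(2-p)/(phi*(2-p)))` is
#' used in closed form; for `y > 0` the Poisson-Gamma series is evaluated by
#' index truncation around its dominant term (Dunn-Smyth style), with relative
#' tail tolerance `tol`.
#'
#' @inheritParams tweedie_unit_deviance
#' @param phi Positive dispersion.
#' @param tol Relative tolerance for dropping series tails.
#' @param max_terms Cap on the number of series terms per observation.
#' @return Numeric vector of log densities.
#' @export
#' @examples
#' tweedie_logpdf(0, mu = 1, phi = 1, p = 1.5)   # -2
tweedie_logpdf <- function(y, mu, phi, p, tol = 1e-12, max_terms = 1e4) {
  check_power(p)
  if (any(phi <= 0)) abort("`phi` must be positive.")
  if (any(y < 0)) abort("`y` must be non-negative.")
  if (any(mu <= 0)) abort("`mu` must be positive.")
  n <- max(length(y), length(mu), length(phi))
  y <- rep_len(y, n); mu <- rep_len(mu, n); phi <- rep_len(phi, n)

  out <- numeric(n)
  pr <- cpg_params(mu, phi, p)
  zero <- y == 0
  out[zero] <- -pr$lambda[zero]
  if (!any(!zero)) return(out)

  yp <- y[!zero]
  lambda <- pr$lambda[!zero]
  gam <- pr$gam[!zero]
  alpha <- pr$alpha
  m <- length(yp)

  # log of the j-th series term (j >= 1), up to the common factor
  # -lambda - y/gam - log(y):
  #   t_j = j*log(lambda) - lgamma(j+1) + (j*alpha)*log(y/gam) - lgamma(j*alpha)
  # Dominant index approximately jmax = y^(2-p) / (phi * (2-p)).
  phip <- phi[!zero]
  jmax <- pmax(1, yp^(2 - p) / (phip * (2 - p)))
  jlo <- pmax(1, floor(jmax / 2))
  jhi <- ceiling(jmax * 2) + 10

  log_y_over_gam <- log(yp) - log(gam)
  log_lambda <- log(lambda)

  term_at <- function(j) {
    # j: integer vector (len m or 1); vectorized over observations
    j * log_lambda - lgamma(j + 1) + j * alpha * log_y_over_gam - lgamma(j * alpha)
  }

  t_peak <- term_at(jmax) # continuous surrogate for scaling only
  acc <- numeric(m)       # sum of exp(t_j - t_peak)

  # expand window downward/upward until all observations' tails are negligible
  add_range <- function(from, to, acc) {
    if (any(to >= from)) {
      for (j in seq(from, to)) {
        acc <- acc + exp(term_at(j) - t_peak)
      }
    }
    acc
  }

  # initial window
  lo <- max(1, min(jlo)); hi <- max(jhi)
  if (hi - lo + 1 > max_terms) {
    abort(sprintf(
      "Tweedie series needs more than %d terms (window %d..%d); increase `max_terms` or check parameters.",
      as.integer(max_terms), lo, hi
    ))
  }
  acc <- add_range(lo, hi, acc)

  # extend upward while the last term is still non-negligible for any obs
  repeat {
    last <- exp(term_at(hi) - t_peak)
    if (all(last <= tol * acc) || hi - lo >= max_terms) break
    new_hi <- hi + max(8, ceiling(0.2 * hi))
    acc <- add_range(hi + 1, new_hi, acc)
    hi <- new_hi
    if (hi - lo >= max_terms) {
      abort("Tweedie series did not converge within `max_terms` terms.")
    }
  }
  # extend downward similarly (window already starts at >= 1)
  while (lo > 1) {
    first <- exp(term_at(lo) - t_peak)
    if (all(first <= tol * acc)) break
    new_lo <- max(1, lo - max(8, ceiling(0.2 * lo)))
    acc <- add_range(new_lo, lo - 1, acc)
    lo <- new_lo
  }

  out[!zero] <- -lambda - yp / gam - log(yp) + t_peak + log(acc)
  out
}

#' Sample from a Tweedie distribution
#'
#' Exact compound Poisson-Gamma sampler: draws `N ~ Poisson(lambda)` then the
#' sum of `N` Gamma(shape `alpha`, scale `gamma`) jumps, so exact zeros occur
#' with probability `exp(-lambda)`.
#'
#' @inheritParams tweedie_logpdf
#' @param n Number of draws.
#' @return Numeric vector of `n` non-negative draws.
#' @export
sample_tweedie <- function(n, mu, phi, p) {
  check_power(p)
  if (any(mu <= 0) || any(phi <= 0)) abort("`mu` and `phi` must be positive.")
  mu <- rep_len(mu, n); phi <- rep_len(phi, n)
  pr <- cpg_params(mu, phi, p)
  counts <- rpois(n, pr$lambda)
  out <- numeric(n)
  pos <- counts > 0
  if (any(pos)) {
    # sum of k iid Gamma(alpha, scale) is Gamma(k * alpha, scale)
    out[pos] <- rgamma(sum(pos), shape = counts[pos] * pr$alpha,
                       scale = pr$gam[pos])
  }
  out
}
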