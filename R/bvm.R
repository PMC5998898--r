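#' Bivariate von Mises distribution, cosine model
#'
#' The density on the torus used to describe a Ramachandran basin:
#' \deqn{f(\phi, \psi) \propto \exp\{\kappa_1\cos(\phi-\mu) +
#'   \kappa_2\cos(\psi-\nu) + \kappa_3\cos(\phi-\mu-\psi+\nu)\}}
#' with locations \eqn{\mu, \nu} (degrees), marginal concentrations
#' \eqn{\kappa_1, \kappa_2 \ge 0} and a real interaction concentration
#' \eqn{\kappa_3}. The normalizing integral has the Bessel series
#' \deqn{(2\pi)^2\{I_0(\kappa_1)I_0(\kappa_2)I_0(\kappa_3) +
#'   2\sum_{p\ge 1} I_p(\kappa_1)I_p(\kappa_2)I_p(\kappa_3)\},}
#' evaluated here in log space with exponentially scaled Bessel functions so
#' concentrations up to 700 stay finite. The density divides by this
#' integral, which makes it integrate to 1 over the torus (verified by
#' quadrature in the test suite).
#'
#' @name bvm
NULL

#' Construct a bivariate von Mises parameter set
#'
#' @param mu,nu location angles in degrees.
#' @param kappa1,kappa2 marginal concentrations, `>= 0`.
#' @param kappa3 interaction concentration (any sign).
#' @return an object of class `bvm_params`.
#' @export
bvm_params <- function(mu, nu, kappa1, kappa2, kappa3 = 0) {
  stopifnot(is.numeric(mu), is.numeric(nu), length(mu) == 1L, length(nu) == 1L)
  if (kappa1 < 0 || kappa2 < 0) {
    stop("`kappa1` and `kappa2` must be non-negative", call. = FALSE)
  }
  structure(
    list(mu = wrap_angle(mu), nu = wrap_angle(nu),
         kappa1 = kappa1, kappa2 = kappa2, kappa3 = kappa3),
    class = "bvm_params"
  )
}

#' @export
print.bvm_params <- function(x, ...) {
  cat(sprintf(
    "<bvm_params> mu = %.2f, nu = %.2f, kappa = (%.3g, %.3g, %.3g)\n",
    x$mu, x$nu, x$kappa1, x$kappa2, x$kappa3))
  invisible(x)
}

# log I_p(x) for x >= 0 via the exponentially scaled Bessel function.
log_besselI <- function(x, p) {
  b <- besselI(x, p, expon.scaled = TRUE)
  ifelse(b > 0, log(b) + x, -Inf)
}

#' Log normalizing integral of the cosine-model density
#'
#' Returns \eqn{\log\int\int \exp\{\kappa_1\cos\phi + \kappa_2\cos\psi +
#' \kappa_3\cos(\phi-\psi)\}\, d\phi\, d\psi} over the torus (radians).
#' For non-negative `kappa3` every series term is positive and the sum is
#' accumulated in log space, truncated when a term's relative contribution
#' drops below `1e-14` (hard cap `p <= 10^4`). For negative `kappa3` the
#' series alternates (\eqn{I_p(-\kappa) = (-1)^p I_p(\kappa)}) and cancels
#' catastrophically at large concentrations, so the psi integral is taken
#' analytically instead: \eqn{\int 2\pi I_0(R(\phi)) e^{\kappa_1\cos\phi}
#' d\phi} with \eqn{R(\phi) = \sqrt{\kappa_2^2 + \kappa_3^2 +
#' 2\kappa_2\kappa_3\cos\phi}}, evaluated on a periodic grid in log space
#' (spectrally accurate for this smooth integrand).
#'
#' @param kappa1,kappa2 concentrations `>= 0`.
#' @param kappa3 interaction concentration (any sign).
#' @return the log integral (a scalar).
#' @examples
#' bvm_log_norm_const(0, 0, 0)  # log((2*pi)^2)
#' @export
bvm_log_norm_const <- function(kappa1, kappa2, kappa3) {
  if (kappa1 < 0 || kappa2 < 0) {
    stop("`kappa1` and `kappa2` must be non-negative", call. = FALSE)
  }
  if (kappa3 < 0) {
    # exact psi reduction: sum of two cosines has amplitude R(phi)
    n <- 4096L
    g <- seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]
    r <- sqrt(kappa2^2 + kappa3^2 + 2 * kappa2 * kappa3 * cos(g))
    lt <- kappa1 * cos(g) + log_besselI(r, 0)
    m <- max(lt)
    if (!is.finite(m)) {
      stop("non-finite Bessel evaluation: concentrations too large",
           call. = FALSE)
    }
    return(log(2 * pi) + log(2 * pi / n) + m + log(sum(exp(lt - m))))
  }
  lt0 <- log_besselI(kappa1, 0) + log_besselI(kappa2, 0) +
    log_besselI(kappa3, 0)
  if (!is.finite(lt0)) {
    stop("non-finite Bessel evaluation: concentrations too large",
         call. = FALSE)
  }
  ls <- lt0
  for (p in seq_len(10000L)) {
    lt <- log(2) + log_besselI(kappa1, p) + log_besselI(kappa2, p) +
      log_besselI(kappa3, p)
    if (!is.finite(lt)) break
    ls <- logspace_add(ls, lt)
    # terms are eventually decreasing; stop once negligible
    if (lt < ls + log(1e-14)) break
  }
  log((2 * pi)^2) + ls
}

logspace_add <- function(la, lb) {
  m <- pmax(la, lb)
  ifelse(is.infinite(m) & m < 0, -Inf, m + log1p(exp(-abs(la - lb))))
}

#' Bivariate von Mises density
#'
#' @param phi,psi angles in degrees (vectors of equal length).
#' @param params a [bvm_params()] object.
#' @param log return the log density?
#' @return density per squared radian (or its log).
#' @export
dbvm <- function(phi, psi, params, log = FALSE) {
  stopifnot(inherits(params, "bvm_params"))
  dphi <- (phi - params$mu) * DEG2RAD
  dpsi <- (psi - params$nu) * DEG2RAD
  lk <- params$kappa1 * cos(dphi) + params$kappa2 * cos(dpsi) +
    params$kappa3 * cos(dphi - dpsi) -
    bvm_log_norm_const(params$kappa1, params$kappa2, params$kappa3)
  if (log) lk else exp(lk)
}

# Univariate von Mises sampler (Best & Fisher 1979 wrapped-Cauchy envelope);
# mu in degrees, returns degrees in [-180, 180).
rvm <- function(n, mu, kappa) {
  if (kappa < 1e-10) {
    return(wrap_angle(stats::runif(n, -180, 180)))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    u2 <- stats::runif(m)
    ok <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    theta <- sign(stats::runif(m) - 0.5) * acos(f)
    theta <- theta[ok]
    take <- length(theta)
    if (take > 0L) {
      out[(got + 1L):(got + take)] <- theta
      got <- got + take
    }
  }
  wrap_angle(mu + out / DEG2RAD)
}

#' Sample from a bivariate von Mises distribution
#'
#' Rejection sampling: propose from the product of the two marginal-location
#' univariate von Mises distributions \eqn{vM(\mu,\kappa_1) \times
#' vM(\nu,\kappa_2)} and accept with probability
#' \eqn{\exp\{\kappa_3\cos(\Delta\phi-\Delta\psi) - |\kappa_3|\}}, which is
#' exact. Efficient when the interaction is moderate relative to the
#' marginal concentrations.
#'
#' @param n number of draws.
#' @param params a [bvm_params()] object.
#' @return a tibble with `phi`, `psi` columns in degrees.
#' @export
rbvm <- function(n, params) {
  stopifnot(inherits(params, "bvm_params"))
  phi <- numeric(n); psi <- numeric(n)
  got <- 0L
  a3 <- abs(params$kappa3)
  while (got < n) {
    m <- max(n - got, 16L)
    p <- rvm(m, params$mu, params$kappa1)
    s <- rvm(m, params$nu, params$kappa2)
    la <- params$kappa3 *
      cos((p - params$mu) * DEG2RAD - (s - params$nu) * DEG2RAD) - a3
    keep <- log(stats::runif(m)) < la
    p <- p[keep]; s <- s[keep]
    take <- min(length(p), n - got)
    if (take > 0L) {
      idx <- (got + 1L):(got + take)
      phi[idx] <- p[seq_len(take)]
      psi[idx] <- s[seq_len(take)]
      got <- got + take
    }
  }
  tibble::tibble(phi = phi, psi = psi)
}

# Invert the von Mises concentration relation A(kappa) = I1/I0 = rbar by
# Newton iteration; A'(k) = 1 - A/k - A^2.
vm_kappa_from_rbar <- function(rbar, cap = 700, tol = 1e-10) {
  if (rbar <= 0) return(0)
  if (rbar >= 1 - 1e-12) return(cap)
  # Best-Fisher starting value
  k <- if (rbar < 0.53) {
    2 * rbar + rbar^3 + 5 * rbar^5 / 6
  } else if (rbar < 0.85) {
    -0.4 + 1.39 * rbar + 0.43 / (1 - rbar)
  } else {
    1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)
  }
  k <- min(max(k, 1e-8), cap)
  for (i in seq_len(100L)) {
    a <- exp(log_besselI(k, 1) - log_besselI(k, 0))
    step <- (a - rbar) / (1 - a / k - a^2)
    k <- k - step
    if (!is.finite(k) || k > cap) return(cap)
    if (k < 1e-12) k <- 1e-12
    if (abs(step) < tol) break
  }
  min(k, cap)
}

#' Method-of-moments estimate of bivariate von Mises parameters
#'
#' Locations are circular means. Marginal concentrations invert
#' \eqn{A(\kappa) = I_1(\kappa)/I_0(\kappa) = \bar R} on each marginal mean
#' resultant length (Newton iteration, tolerance `1e-10`, cap 700). The
#' interaction magnitude inverts the same relation on the mean resultant
#' length of the deviation differences \eqn{(\phi-\mu)-(\psi-\nu)}, with the
#' sign taken from the circular correlation of the deviations
#' \eqn{\sum \sin(\phi-\mu)\sin(\psi-\nu)}.
#'
#' @param phi,psi angle samples in degrees (`NA` pairs dropped); at least 10
#'   complete pairs required.
#' @param kappa_cap concentration cap (default 700).
#' @return a [bvm_params()] object.
#' @export
estimate_bvm <- function(phi, psi, kappa_cap = 700) {
  keep <- !is.na(phi) & !is.na(psi)
  phi <- phi[keep]; psi <- psi[keep]
  if (length(phi) < 10L) {
    stop("insufficient data: at least 10 complete angle pairs required",
         call. = FALSE)
  }
  sp <- circular_summary(phi)
  ss <- circular_summary(psi)
  k1 <- vm_kappa_from_rbar(sp$rbar, cap = kappa_cap)
  k2 <- vm_kappa_from_rbar(ss$rbar, cap = kappa_cap)
  dphi <- (phi - sp$mean) * DEG2RAD
  dpsi <- (psi - ss$mean) * DEG2RAD
  delta <- wrap_angle((dphi - dpsi) / DEG2RAD)
  k3 <- vm_kappa_from_rbar(circular_summary(delta)$rbar, cap = kappa_cap)
  if (sum(sin(dphi) * sin(dpsi)) < 0) k3 <- -k3
  bvm_params(sp$mean, ss$mean, k1, k2, k3)
}

#' Mean log-likelihood of angle pairs under a basin mixture
#'
#' \deqn{LL = \frac{1}{N}\sum_i \log \sum_k p_{ik} f_k(\phi_i, \psi_i)}
#' evaluated with log-sum-exp stabilisation. Residues with undefined angles
#' are excluded.
#'
#' @param phi,psi angles in degrees, length L.
#' @param probs L x K matrix of per-residue mixture probabilities; rows must
#'   sum to 1 within `1e-9`.
#' @param params list of K [bvm_params()] objects.
#' @return mean log-likelihood in nats (density per squared radian). If the
#'   mixture density vanishes at some residue the result is `-Inf` and
#'   carries an attribute `n_zero` with the count of such residues.
#' @export
bvm_mixture_loglik <- function(phi, psi, probs, params) {
  probs <- as.matrix(probs)
  K <- length(params)
  if (ncol(probs) != K) {
    stop("`probs` must have one column per mixture component", call. = FALSE)
  }
  if (nrow(probs) != length(phi) || length(phi) != length(psi)) {
    stop("`probs` rows must match the number of angle pairs", call. = FALSE)
  }
  if (any(abs(rowSums(probs) - 1) > 1e-9) || any(probs < -1e-12)) {
    stop("`probs` rows must lie on the probability simplex", call. = FALSE)
  }
  keep <- !is.na(phi) & !is.na(psi)
  phi <- phi[keep]; psi <- psi[keep]
  probs <- probs[keep, , drop = FALSE]
  lf <- vapply(params, function(p) dbvm(phi, psi, p, log = TRUE),
               numeric(length(phi)))
  lf <- matrix(lf, nrow = length(phi))
  lw <- lf + log(pmax(probs, 0))      # -Inf where p = 0
  m <- apply(lw, 1L, max)
  li <- ifelse(is.finite(m),
               m + log(rowSums(exp(lw - ifelse(is.finite(m), m, 0)))),
               -Inf)
  nz <- sum(!is.finite(li))
  out <- if (nz > 0L) -Inf else mean(li)
  if (nz > 0L) attr(out, "n_zero") <- nz
  out
}
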