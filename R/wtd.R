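#' Waiting-time and inter-event-time densities on an equidistant grid
#'
#' Densities are represented as piecewise-constant functions on equidistant,
#' half-open bins `[left, right)` covering `[0, tau_max]`, plus a single tail
#' atom holding whatever probability mass lies beyond the grid.  The survival
#' function is evaluated exactly as the right-tail bin sum (so `S(0) = 1` and
#' `S(tau_max) = tail`), and the hazard is piecewise constant,
#' `lambda(tau) = psi(tau) / max(S(tau), floor)`.
#'
#' @param breaks numeric vector of bin edges, equidistant, starting at 0.
#' @param dens per-bin density values (length `length(breaks) - 1`).
#' @param tail probability mass beyond the last edge (a single atom).
#' @param h kernel bandwidth used when the density was constructed (or `NA`).
#' @return an object of class `stn_wtd`.
#' @export
new_wtd <- function(breaks, dens, tail = 0, h = NA_real_) {
  stopifnot(is.numeric(breaks), length(breaks) >= 2,
            length(dens) == length(breaks) - 1)
  if (abs(breaks[1]) > 1e-12) stop("grid must start at 0")
  dx <- diff(breaks)
  if (max(dx) - min(dx) > 1e-9 * dx[1]) stop("grid must be equidistant")
  if (any(dens < -1e-12) || tail < -1e-12)
    stop("density values must be non-negative")
  dens <- pmax(dens, 0)
  tail <- max(tail, 0)
  tot <- sum(dens * dx[1]) + tail
  if (abs(tot - 1) > 1e-9)
    stop("density must integrate to 1 over the grid (got ", format(tot), ")")
  structure(list(breaks = as.numeric(breaks), dens = as.numeric(dens),
                 tail = tail, h = h),
            class = "stn_wtd")
}

#' Build a density from per-bin probability masses (normalising)
#'
#' @inheritParams new_wtd
#' @param mass per-bin probability mass (not density); normalised together
#'   with `tail` to total mass 1.
#' @return an `stn_wtd`.
#' @export
wtd_from_mass <- function(mass, breaks, tail = 0, h = NA_real_) {
  dx <- breaks[2] - breaks[1]
  tot <- sum(mass) + tail
  if (tot <= 0) stop("total mass must be positive")
  new_wtd(breaks, mass / tot / dx, tail / tot, h)
}

#' @export
print.stn_wtd <- function(x, ...) {
  nb <- length(x$dens)
  cat(sprintf("<stn_wtd> %d bins on [0, %.4g], dx = %.4g, tail mass = %.3g, mean = %.4g\n",
              nb, x$breaks[nb + 1], x$breaks[2] - x$breaks[1], x$tail,
              wtd_mean(x)))
  invisible(x)
}

wtd_dx <- function(w) w$breaks[2] - w$breaks[1]
wtd_nbins <- function(w) length(w$dens)

#' Mean of a binned density (bin midpoints; tail atom sits at the last edge)
#' @param w an `stn_wtd`.
#' @return numeric mean.
#' @export
wtd_mean <- function(w) {
  dx <- wtd_dx(w)
  mid <- w$breaks[-length(w$breaks)] + dx / 2
  sum(mid * w$dens * dx) + w$tail * w$breaks[length(w$breaks)]
}

#' Survival function values at all bin edges
#'
#' `S[j]` is the survival at the j-th edge: the mass in bins `j..nb` plus the
#' tail atom; `S[1] = 1`, `S[nb + 1] = tail`.
#' @param w an `stn_wtd`.
#' @return numeric vector of length `nbins + 1`.
#' @export
wtd_surv_edges <- function(w) {
  dx <- wtd_dx(w)
  c(rev(cumsum(rev(w$dens * dx))) + w$tail, w$tail)
}

# half-open bin lookup; returns nbins + 1 for tau at/beyond the last edge.
# the small relative nudge keeps taus that are exact bin edges in the bin to
# their right, matching the [left, right) convention under floating point.
wtd_bin <- function(w, tau) {
  dx <- wtd_dx(w)
  nb <- wtd_nbins(w)
  i <- floor(tau / dx + 1e-9) + 1L
  pmin(pmax(i, 1L), nb + 1L)
}

#' Survival function S(tau) of a waiting-time density
#'
#' @param w an `stn_wtd`.
#' @param tau non-negative times (vectorised).
#' @return `P(wait > tau)`, evaluated by half-open bin lookup; times at or
#'   beyond the grid return the tail mass.
#' @export
wtd_survival <- function(w, tau) {
  if (any(tau < 0)) stop("tau must be >= 0")
  wtd_surv_edges(w)[wtd_bin(w, tau)]
}

#' Hazard function lambda(tau) = psi(tau) / S(tau)
#'
#' The survival in the denominator is floored (default `1e-12`) and the
#' result capped (default `1e12`) so that log-likelihoods stay finite.
#' Beyond the grid the tail atom is treated as one extra bin of width `dx`.
#'
#' @inheritParams wtd_survival
#' @return non-negative hazard rates.
#' @export
wtd_hazard <- function(w, tau) {
  if (any(tau < 0)) stop("tau must be >= 0")
  i <- wtd_bin(w, tau)
  s <- wtd_surv_edges(w)[i]
  dens_ext <- c(w$dens, w$tail / wtd_dx(w))
  pmin(dens_ext[i] / pmax(s, .stn_s_floor), .stn_lambda_max)
}

#' Draw waiting times from a binned density
#'
#' Samples a bin proportionally to its mass (uniform within the bin); a draw
#' landing in the tail atom returns the last grid edge.
#' @param w an `stn_wtd`.
#' @param m number of draws.
#' @return numeric vector of length `m`.
#' @export
wtd_sample <- function(w, m) {
  dx <- wtd_dx(w)
  nb <- wtd_nbins(w)
  p <- c(w$dens * dx, w$tail)
  b <- sample.int(nb + 1L, m, replace = TRUE, prob = p)
  tau <- w$breaks[pmin(b, nb)] + runif(m) * dx
  tau[b == nb + 1L] <- w$breaks[nb + 1]
  tau
}

#' Inter-event-time density
#'
#' Same binned representation as [new_wtd()] but for the IET law `rho(tau)` of
#' a link's renewal event sequence; carries its mean, which must be positive
#' for the length-biased transform to exist.
#'
#' @inheritParams new_wtd
#' @return an object of class `stn_iet`.
#' @export
new_iet <- function(breaks, dens) {
  w <- new_wtd(breaks, dens, tail = 0)
  dx <- wtd_dx(w)
  mid <- breaks[-length(breaks)] + dx / 2
  mu <- sum(mid * dens * dx)
  if (!is.finite(mu) || mu <= 0)
    stop("IET density has zero or undefined mean; cannot form a waiting-time law")
  structure(list(breaks = w$breaks, dens = w$dens, mean = mu),
            class = "stn_iet")
}

#' Length-biased waiting-time law of an inter-event-time density
#'
#' When a node becomes informed at a uniformly random instant of a stationary
#' renewal sequence with IET density `rho`, the residual wait until the next
#' activation follows the inspection-paradox (length-biased) law
#' `psi(tau) = S_rho(tau) / mu`, where `S_rho` is the IET survival and `mu`
#' the IET mean.  For exponential IETs this is the identity (memorylessness);
#' for an IET degenerate at `Delta` it is uniform on `[0, Delta]`.
#'
#' The integral of `S_rho / mu` over each bin is computed exactly for the
#' piecewise-constant `rho` (trapezoid of the piecewise-linear survival).
#'
#' @param iet an `stn_iet` with positive mean.
#' @return an `stn_wtd` on the same grid.
#' @export
length_biased_wtd <- function(iet) {
  if (!inherits(iet, "stn_iet")) stop("`iet` must be an stn_iet")
  dx <- iet$breaks[2] - iet$breaks[1]
  mass <- iet$dens * dx
  s_edges <- pmax(1 - cumsum(c(0, mass)), 0)   # survival of rho at edges
  nb <- length(iet$dens)
  psi_mass <- (s_edges[-(nb + 1)] + s_edges[-1]) / 2 * dx / iet$mean
  tail <- max(0, 1 - sum(psi_mass))
  wtd_from_mass(psi_mass, iet$breaks, tail = tail)
}

#' Discretise a parametric waiting-time density onto a grid
#'
#' Families: `"gaussian"` (truncated at 0; parameters `mean`, `sd`),
#' `"exponential"` (`mean` or `rate`), `"uniform"` (`min`, `max`),
#' `"pareto"` (`xm`, `alpha`), `"lognormal"` (`meanlog`, `sdlog`).
#' Per-bin masses are exact CDF differences; mass beyond the grid becomes the
#' tail atom.
#'
#' @param family density family name.
#' @param params named list of family parameters.
#' @param tau_max grid upper end; defaults to a high quantile of the family.
#' @param nbins number of equidistant bins.
#' @return an `stn_wtd`.
#' @export
wtd_parametric <- function(family = c("gaussian", "exponential", "uniform",
                                      "pareto", "lognormal"),
                           params = list(), tau_max = NULL, nbins = 400) {
  family <- match.arg(family)
  p <- params
  cdf <- switch(family,
    gaussian = {
      m <- p$mean %||% 2; s <- p$sd %||% 0.5
      f0 <- pnorm(0, m, s)
      function(x) (pnorm(x, m, s) - f0) / (1 - f0)
    },
    exponential = {
      rate <- p$rate %||% (1 / (p$mean %||% 1))
      function(x) pexp(x, rate)
    },
    uniform = {
      a <- p$min %||% 0; b <- p$max %||% 2
      function(x) punif(x, a, b)
    },
    pareto = {
      xm <- p$xm %||% 1; al <- p$alpha %||% 2.5
      if (al <= 1) stop("pareto alpha must exceed 1 for a finite mean")
      function(x) ifelse(x < xm, 0, 1 - (xm / x)^al)
    },
    lognormal = {
      ml <- p$meanlog %||% 0; sl <- p$sdlog %||% 0.5
      function(x) plnorm(x, ml, sl)
    })
  if (is.null(tau_max)) {
    q <- switch(family,
      gaussian    = (p$mean %||% 2) + 6 * (p$sd %||% 0.5),
      exponential = qexp(1 - 1e-6, p$rate %||% (1 / (p$mean %||% 1))),
      uniform     = p$max %||% 2,
      pareto      = (p$xm %||% 1) * (1e-4)^(-1 / (p$alpha %||% 2.5)),
      lognormal   = qlnorm(1 - 1e-4, p$meanlog %||% 0, p$sdlog %||% 0.5))
    tau_max <- q
  }
  breaks <- seq(0, tau_max, length.out = nbins + 1)
  mass <- pmax(diff(cdf(breaks)), 0)
  tail <- max(0, 1 - cdf(tau_max))
  wtd_from_mass(mass, breaks, tail = tail)
}

#' Kolmogorov-Smirnov divergence between two densities on the same grid
#'
#' The sup-norm distance between the two survival functions evaluated at the
#' bin edges; used as the convergence criterion of the self-consistent
#' waiting-time estimator.
#'
#' @param a,b `stn_wtd` objects on identical grids.
#' @return non-negative scalar.
#' @export
ks_divergence <- function(a, b) {
  if (!inherits(a, "stn_wtd") || !inherits(b, "stn_wtd"))
    stop("arguments must be stn_wtd objects")
  if (length(a$breaks) != length(b$breaks) ||
      max(abs(a$breaks - b$breaks)) > 1e-9)
    stop("densities live on different grids")
  max(abs(wtd_surv_edges(a) - wtd_surv_edges(b)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# gaussian smoothing of a per-bin mass vector by a kernel of bandwidth h,
# discretised on bin offsets; mass pushed below 0 is dropped (the caller
# renormalises).  h = 0 or kernel "dirac" is the identity.
smooth_mass <- function(mass, dx, h, kernel = "gaussian") {
  if (kernel == "dirac" || is.na(h) || h <= 0) return(mass)
  m <- max(1L, ceiling(4 * h / dx))
  off <- (-m):m
  kmass <- pnorm((off + 0.5) * dx, 0, h) - pnorm((off - 0.5) * dx, 0, h)
  kmass <- kmass / sum(kmass)
  nb <- length(mass)
  out <- numeric(nb)
  for (k in seq_along(off)) {
    s <- off[k]
    src <- seq_len(nb)
    dst <- src + s
    ok <- dst >= 1 & dst <= nb
    out[dst[ok]] <- out[dst[ok]] + mass[src[ok]] * kmass[k]
  }
  out
}
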