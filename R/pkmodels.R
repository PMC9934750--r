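## Tracer-kinetic forward models and per-curve fitting.
##
## Tissue concentration is modeled as the convolution of the plasma input
## Cp(t) with one (Tofts) or two (two-tissue compartment model, 2TCM)
## exponential washout kernels:
##
##   Tofts:  C(t) = Ktrans * int_0^t Cp(tau) exp(-(t - tau) kep) dtau
##   2TCM:   C(t) = int_0^t Cp(tau) [ K1trans exp(-(t - tau) kep1)
##                                  + K2trans exp(-(t - tau) kep2) ] dtau
##
## For fitting, the 2TCM is reparameterized in an asymmetric form that makes
## the solution unique: K2trans = eps * K1trans, kep2 = kep1 + lam with
## lam >= 0, i.e. the kernel becomes
##   exp(-(t - tau) kep1) * [1 + eps * exp(-(t - tau) lam)].
## The amplitude ordering (K1trans = the larger amplitude) is restored after
## the fit by canonicalize2TCM().

# phi1(x) = (1 - exp(-x))/x, phi2(x) = (1 - exp(-x)(1 + x))/x^2, both with
# stable small-x series; phi1(0) = 1, phi2(0) = 1/2.
.phi12 <- function(x) {
  phi1 <- numeric(length(x))
  phi2 <- numeric(length(x))
  small <- x < 1e-4
  xs <- x[small]
  phi1[small] <- 1 - xs / 2 + xs^2 / 6 - xs^3 / 24
  phi2[small] <- 0.5 - xs / 3 + xs^2 / 8 - xs^3 / 30
  xl <- x[!small]
  e <- exp(-xl)
  phi1[!small] <- (1 - e) / xl
  phi2[!small] <- (1 - e * (1 + xl)) / xl^2
  list(phi1 = phi1, phi2 = phi2)
}

.asCp <- function(aif) {
  if (is(aif, "AIF"))
    list(cp = aif@cpMM, times = aif@timesMin)
  else if (is.list(aif) && !is.null(aif$cp) && !is.null(aif$times))
    list(cp = aif$cp, times = aif$times)
  else stop("aif must be an AIF object or a list(cp=, times=)")
}

#' Exact convolution of a sampled curve with an exponential kernel
#'
#' Computes `int_0^t cp(tau) exp(-k (t - tau)) dtau` on the sampling grid,
#' treating `cp` as piecewise linear between samples. Each interval is
#' integrated in closed form and chained by the recursion
#' `I(t_{i+1}) = I(t_i) exp(-k dt) + a_i`, so the result is exact for the
#' interpolant (no quadrature error); for `k = 0` it reduces to the
#' cumulative trapezoid integral.
#'
#' @param cp sampled input curve (e.g. plasma concentration, mM).
#' @param timesMin sample times in minutes, strictly increasing,
#'   `timesMin[1]` is taken as t = 0 of the convolution.
#' @param k exponential rate constant (min^-1), must be >= 0.
#' @return numeric vector of the convolved curve on the same grid;
#'   the first element is 0.
#' @examples
#' t <- seq(0, 5, by = 0.1)
#' expConvolve(rep(1, length(t)), t, k = 0.5)  # (1 - exp(-0.5 t)) / 0.5
#' @export
expConvolve <- function(cp, timesMin, k) {
  if (length(k) != 1L || !is.finite(k) || k < 0)
    stop("k must be a single finite value >= 0")
  if (length(cp) != length(timesMin))
    stop("cp and timesMin must share length")
  n <- length(cp)
  if (n < 2L) return(numeric(n))
  dt <- diff(timesMin)
  if (any(dt <= 0)) stop("timesMin must be strictly increasing")
  cpL <- cp[-n]
  cpR <- cp[-1L]
  uniform <- max(dt) - min(dt) < 1e-12 * max(dt)
  if (uniform) {
    h <- dt[1]
    x <- k * h
    ph <- .phi12(x)
    a <- h * (cpR * ph$phi1 + (cpL - cpR) * ph$phi2)
    E <- exp(-x)
    # linear recurrence I[i+1] = E * I[i] + a[i], I[1] = 0
    out <- c(0, as.numeric(stats::filter(a, E, method = "recursive")))
  } else {
    x <- k * dt
    ph <- .phi12(x)
    a <- dt * (cpR * ph$phi1 + (cpL - cpR) * ph$phi2)
    E <- exp(-x)
    out <- numeric(n)
    for (i in seq_len(n - 1L)) out[i + 1L] <- out[i] * E[i] + a[i]
  }
  out
}

#' Tofts model forward curve
#'
#' `C(t) = ktrans * int_0^t Cp(tau) exp(-(t - tau) kep) dtau`.
#'
#' @param params named list or vector with `ktrans` and `kep` (min^-1).
#' @param aif an [AIF-class] object or `list(cp=, times=)` (mM / minutes).
#' @return tissue concentration curve (mM) on the AIF time grid.
#' @export
toftsForward <- function(params, aif) {
  p <- as.list(params)
  if (p$ktrans < 0 || p$kep < 0) stop("ktrans and kep must be >= 0")
  a <- .asCp(aif)
  p$ktrans * expConvolve(a$cp, a$times, p$kep)
}

#' Two-tissue compartment model forward curve
#'
#' One fast and one slow exchanging compartment. Accepts either the
#' fit-space parameterization (`k1trans`, `kep1`, `eps`, `lam`; the factored
#' kernel `exp(-u kep1) [1 + eps exp(-u lam)]`, `lam >= 0`) or the amplitude
#' parameterization (`k1trans`, `kep1`, `k2trans`, `kep2`; the explicit
#' two-exponential sum). Both give identical curves to machine precision for
#' corresponding parameters (`k2trans = eps k1trans`, `kep2 = kep1 + lam`).
#'
#' @param params named list/vector in either parameterization (min^-1 rates,
#'   `eps` dimensionless).
#' @param aif an [AIF-class] object or `list(cp=, times=)`.
#' @param form `"factored"` evaluates the factored kernel (fit-space
#'   arithmetic), `"two-term"` the explicit two-exponential sum. Given
#'   fit-space parameters, `"two-term"` first expands them to amplitudes.
#' @return tissue concentration curve (mM) on the AIF time grid.
#' @export
twoTCMForward <- function(params, aif, form = c("factored", "two-term")) {
  form <- match.arg(form)
  p <- as.list(params)
  a <- .asCp(aif)
  fitSpace <- !is.null(p$eps)
  if (fitSpace) {
    if (p$lam < 0) stop("lam must be >= 0 in the fit-space parameterization")
    if (p$eps < 0 || p$k1trans < 0 || p$kep1 < 0)
      stop("k1trans, kep1, eps must be >= 0")
  } else {
    if (any(c(p$k1trans, p$kep1, p$k2trans, p$kep2) < 0))
      stop("all rates and amplitudes must be >= 0")
  }
  if (form == "factored") {
    if (!fitSpace) {
      p$eps <- if (p$k1trans > 0) p$k2trans / p$k1trans else 0
      p$lam <- p$kep2 - p$kep1
      if (p$lam < 0) { # factored form requires kep2 >= kep1; swap roles
        tmp <- p
        p$k1trans <- tmp$k2trans; p$kep1 <- tmp$kep2
        p$eps <- if (tmp$k2trans > 0) tmp$k1trans / tmp$k2trans else 0
        p$lam <- tmp$kep1 - tmp$kep2
      }
    }
    p$k1trans * (expConvolve(a$cp, a$times, p$kep1) +
                   p$eps * expConvolve(a$cp, a$times, p$kep1 + p$lam))
  } else {
    if (fitSpace) {
      p$k2trans <- p$eps * p$k1trans
      p$kep2 <- p$kep1 + p$lam
    }
    p$k1trans * expConvolve(a$cp, a$times, p$kep1) +
      p$k2trans * expConvolve(a$cp, a$times, p$kep2)
  }
}

#' Root-mean-square error between two sampled curves
#'
#' @param c measured curve (mM).
#' @param fitCurve fitted curve (mM), same length.
#' @return `sqrt(mean((c - fitCurve)^2))`.
#' @export
rmse <- function(c, fitCurve) {
  if (length(c) != length(fitCurve))
    stop("curves must share length")
  sqrt(mean((c - fitCurve)^2))
}

#' Canonical amplitude ordering for two-tissue compartment parameters
#'
#' Either compartment can carry the larger transfer constant depending on
#' whether `eps` exceeds 1. For comparability across voxels, the larger
#' amplitude is always labeled `k1trans` with its paired efflux rate as
#' `kep1`. At exactly equal amplitudes the compartment with the larger efflux
#' rate (the "fast" one) takes the 1 label. Idempotent.
#'
#' @param raw named list/vector in fit-space (`k1trans`, `kep1`, `eps`,
#'   `lam`) or amplitude form (`k1trans`, `kep1`, `k2trans`, `kep2`).
#' @return named list `k1trans, kep1, k2trans, kep2, ve1, ve2` with
#'   `k1trans >= k2trans` and pairing preserved.
#' @export
canonicalize2TCM <- function(raw) {
  p <- as.list(raw)
  if (!is.null(p$eps)) {
    a1 <- p$k1trans; r1 <- p$kep1
    a2 <- p$eps * p$k1trans; r2 <- p$kep1 + p$lam
  } else {
    a1 <- p$k1trans; r1 <- p$kep1
    a2 <- p$k2trans; r2 <- p$kep2
  }
  if (!all(is.finite(c(a1, a2)))) stop("amplitudes must be finite")
  if (a2 > a1 || (a2 == a1 && r2 > r1)) {
    tmp <- a1; a1 <- a2; a2 <- tmp
    tmp <- r1; r1 <- r2; r2 <- tmp
  }
  list(k1trans = a1, kep1 = r1, k2trans = a2, kep2 = r2,
       ve1 = if (r1 > 0) a1 / r1 else NA_real_,
       ve2 = if (r2 > 0) a2 / r2 else NA_real_)
}

.newKineticFit <- function(model, params, c, fitted, converged, nIter) {
  res <- c - fitted
  new("KineticFit", model = model, params = params,
      rmse = sqrt(mean(res^2)), converged = converged,
      nIter = as.integer(nIter), residuals = res, fitted = fitted)
}

# one bounded Levenberg-Marquardt run; returns list(par, sse, converged, nIter)
.lmFit <- function(residFun, start, lower, upper) {
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                       fn = residFun,
                       control = minpack.lm::nls.lm.control(
                         ftol = 1e-10, ptol = 1e-10, maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(par = start, sse = sum(residFun(start)^2),
                converged = FALSE, nIter = 0L))
  list(par = fit$par, sse = fit$deviance,
       converged = fit$info %in% 1:4, nIter = fit$niter)
}

#' Fit the standard Tofts model to one concentration curve
#'
#' Bounded Levenberg-Marquardt least squares of the Tofts forward curve
#' against the measured concentration, from several deterministic starting
#' points; the lowest sum of squares wins.
#'
#' @param c measured concentration curve (mM) on the AIF time grid.
#' @param aif an [AIF-class] object or `list(cp=, times=)`.
#' @param starts matrix-like list of starting values; each element a numeric
#'   `c(ktrans, kep)`. Defaults span slow to fast enhancement.
#' @param bounds list with `lower` and `upper`, each `c(ktrans, kep)`;
#'   defaults `[0, 5] x [0, 10]` min^-1.
#' @return a [KineticFit-class] with params `ktrans`, `kep`, `ve`.
#' @export
fitTofts <- function(c, aif,
                     starts = list(c(0.05, 0.3), c(0.3, 1.0), c(1.0, 2.5)),
                     bounds = list(lower = c(0, 0), upper = c(5, 10))) {
  a <- .asCp(aif)
  if (length(c) != length(a$times))
    stop("curve and AIF must share the time grid")
  if (all(c == 0)) {
    return(.newKineticFit("tofts",
                          list(ktrans = 0, kep = 0, ve = NA_real_),
                          c, fitted = numeric(length(c)),
                          converged = TRUE, nIter = 0L))
  }
  residFun <- function(par)
    c - par[1] * expConvolve(a$cp, a$times, par[2])
  best <- NULL
  for (s in starts) {
    r <- .lmFit(residFun, s, bounds$lower, bounds$upper)
    if (is.null(best) || r$sse < best$sse) best <- r
  }
  ktrans <- best$par[1]; kep <- best$par[2]
  .newKineticFit("tofts",
                 list(ktrans = ktrans, kep = kep,
                      ve = if (kep > 0) ktrans / kep else NA_real_),
                 c, fitted = ktrans * expConvolve(a$cp, a$times, kep),
                 converged = best$converged, nIter = best$nIter)
}

#' Fit the two-tissue compartment model to one concentration curve
#'
#' Bounded Levenberg-Marquardt least squares in the fit-space
#' parameterization (`k1trans`, `kep1`, `eps`, `lam >= 0`), multistart.
#' A Tofts fit is computed first and seeds the starts; one start is the exact
#' Tofts solution with `eps = 0`, which guarantees the returned RMSE never
#' exceeds the Tofts RMSE (model nesting). The winning fit-space solution is
#' passed through [canonicalize2TCM()].
#'
#' @param c measured concentration curve (mM) on the AIF time grid.
#' @param aif an [AIF-class] object or `list(cp=, times=)`.
#' @param toftsFit optional precomputed [fitTofts()] result for this curve;
#'   computed internally when NULL.
#' @param bounds list with `lower`/`upper` over `(k1trans, kep1, eps, lam)`;
#'   defaults `[0,5] x [0,10] x [0,100] x [0,10]`.
#' @return a [KineticFit-class] with canonical params `k1trans, kep1,
#'   k2trans, kep2, ve1, ve2` plus the raw fit-space `eps`, `lam`.
#' @export
fit2TCM <- function(c, aif, toftsFit = NULL,
                    bounds = list(lower = c(0, 0, 0, 0),
                                  upper = c(5, 10, 100, 10))) {
  a <- .asCp(aif)
  if (length(c) != length(a$times))
    stop("curve and AIF must share the time grid")
  if (all(c == 0)) {
    return(.newKineticFit("2tcm",
                          list(k1trans = 0, kep1 = 0, k2trans = 0, kep2 = 0,
                               ve1 = NA_real_, ve2 = NA_real_,
                               eps = 0, lam = 0),
                          c, fitted = numeric(length(c)),
                          converged = TRUE, nIter = 0L))
  }
  if (is.null(toftsFit)) toftsFit <- fitTofts(c, aif)
  ktT <- max(toftsFit@params$ktrans, 1e-4)
  kepT <- max(toftsFit@params$kep, 1e-3)
  clip <- function(s) pmin(pmax(s, bounds$lower), bounds$upper)
  starts <- list(
    c(ktT, kepT, 0, 1.0),                     # exact Tofts solution: nesting
    c(ktT * 0.9, kepT, 0.1, 1.0),             # near-Tofts, small 2nd pool
    c(ktT * 0.2, kepT * 0.25, 4.0, kepT),     # slow-first, dominant fast pool
    c(ktT * 0.5, kepT * 0.5, 1.0, 0.5),       # balanced compartments
    c(ktT * 0.1, 0.1, 8.0, max(kepT, 0.5)))   # strongly asymmetric
  starts <- lapply(starts, clip)
  residFun <- function(par)
    c - par[1] * (expConvolve(a$cp, a$times, par[2]) +
                    par[3] * expConvolve(a$cp, a$times, par[2] + par[4]))
  best <- NULL
  for (s in starts) {
    r <- .lmFit(residFun, s, bounds$lower, bounds$upper)
    if (is.null(best) || r$sse < best$sse) best <- r
  }
  par <- best$par
  fitSpace <- list(k1trans = par[1], kep1 = par[2], eps = par[3],
                   lam = par[4])
  can <- canonicalize2TCM(fitSpace)
  fitted <- par[1] * (expConvolve(a$cp, a$times, par[2]) +
                        par[3] * expConvolve(a$cp, a$times, par[2] + par[4]))
  .newKineticFit("2tcm", c(can, fitSpace[c("eps", "lam")]),
                 c, fitted = fitted,
                 converged = best$converged, nIter = best$nIter)
}
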