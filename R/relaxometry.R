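## VFA T1 mapping and the nonlinear SPGR signal <-> concentration conversion.

#' Spoiled gradient echo (SPGR) signal equation
#'
#' `S = M0 sin(a) (1 - E1) / (1 - E1 cos(a))` with `E1 = exp(-TR/T1)`.
#' Vectorized over `m0`, `t1S` and `flipDeg` (usual recycling rules).
#'
#' @param m0 equilibrium signal (arbitrary units).
#' @param t1S longitudinal relaxation time (seconds), > 0.
#' @param trMs repetition time (ms), > 0.
#' @param flipDeg flip angle (degrees), in (0, 90].
#' @return signal in the same units as `m0`.
#' @export
spgrSignal <- function(m0, t1S, trMs, flipDeg) {
  if (any(t1S <= 0, na.rm = TRUE)) stop("t1S must be positive")
  if (trMs <= 0) stop("trMs must be positive")
  if (any(flipDeg <= 0 | flipDeg > 90)) stop("flipDeg must be in (0, 90]")
  a <- flipDeg * pi / 180
  E1 <- exp(-(trMs / 1000) / t1S)
  m0 * sin(a) * (1 - E1) / (1 - E1 * cos(a))
}

# linearized DESPOT1 estimate for one voxel: regress S/sin(a) on S/tan(a);
# slope = E1, intercept = M0 (1 - E1)
.vfaLinearized <- function(sig, sinA, tanA, trS) {
  y <- sig / sinA
  x <- sig / tanA
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) return(NULL)
  slope <- sum((x - mx) * (y - my)) / sxx
  if (!is.finite(slope) || slope <= 0 || slope >= 1) return(NULL)
  m0 <- (my - slope * mx) / (1 - slope)
  if (!is.finite(m0) || m0 <= 0) return(NULL)
  c(t1 = -trS / log(slope), m0 = m0)
}

#' Variable flip angle T1 mapping
#'
#' Per voxel, estimates (T1, M0) from SPGR signals at multiple flip angles.
#' A linearized DESPOT1 regression (`S/sin(a)` on `S/tan(a)`, slope =
#' `exp(-TR/T1)`) provides the estimate, optionally polished by bounded
#' nonlinear least squares on the SPGR equation itself. Voxels whose slope
#' falls outside (0, 1) — including all-zero voxels — are flagged invalid,
#' never silently zeroed.
#'
#' @param vfa a [VFASeries-class].
#' @param refine polish the linearized estimate with Levenberg-Marquardt
#'   (default TRUE).
#' @param mask optional logical 3D array restricting which voxels are fitted.
#' @return a [T1Map-class].
#' @export
fitVFAT1 <- function(vfa, refine = TRUE, mask = NULL) {
  stopifnot(is(vfa, "VFASeries"))
  d <- dim(vfa@signal)
  nvox <- prod(d[1:3])
  sig <- matrix(vfa@signal, nrow = nvox)
  aRad <- vfa@flipAnglesDeg * pi / 180
  sinA <- sin(aRad); cosA <- cos(aRad); tanA <- tan(aRad)
  trS <- vfa@trMs / 1000
  t1 <- rep(NA_real_, nvox)
  m0 <- rep(NA_real_, nvox)
  ok <- rep(FALSE, nvox)
  idx <- if (is.null(mask)) seq_len(nvox) else which(as.vector(mask))
  for (v in idx) {
    s <- sig[v, ]
    if (all(s == 0) || any(!is.finite(s))) next
    est <- .vfaLinearized(s, sinA, tanA, trS)
    if (is.null(est)) next
    if (refine) {
      residFun <- function(par) {
        E1 <- exp(-trS / par[1])
        s - par[2] * sinA * (1 - E1) / (1 - E1 * cosA)
      }
      fit <- tryCatch(
        minpack.lm::nls.lm(par = c(est["t1"], est["m0"]),
                           lower = c(1e-3, 0), upper = c(20, Inf),
                           fn = residFun,
                           control = minpack.lm::nls.lm.control(
                             ftol = 1e-12, ptol = 1e-12, maxiter = 100)),
        error = function(e) NULL)
      if (!is.null(fit) && is.finite(fit$par[1]) && fit$par[1] > 0)
        est <- c(t1 = unname(fit$par[1]), m0 = unname(fit$par[2]))
    }
    t1[v] <- est["t1"]
    m0[v] <- est["m0"]
    ok[v] <- TRUE
  }
  new("T1Map", t1S = array(t1, d[1:3]), m0 = array(m0, d[1:3]),
      validMask = array(ok, d[1:3]))
}

#' Convert a dynamic signal series to contrast-agent concentration
#'
#' For each voxel with a valid pre-contrast T1 (`T10`), the equilibrium
#' signal M0 is calibrated from the average of the baseline (pre-contrast)
#' frames via the SPGR equation at T10. Each frame's signal is then inverted
#' through the nonlinear SPGR equation for `E1(t)`, giving
#' `T1(t) = -TR / log(E1(t))` and
#' `C(t) = (1/T1(t) - 1/T10) / r1`.
#'
#' Frames whose signal falls outside the invertible range of the SPGR
#' equation (`E1` outside (0, 1)) are flagged NA; voxels invalid in the T1
#' map are skipped entirely (all NA).
#'
#' @param dyn a [DynamicSeries-class].
#' @param t1map a [T1Map-class] on the same grid.
#' @param relaxivityR1 longitudinal relaxivity r1 (s^-1 mM^-1); default 5.5,
#'   a gadobenate-class agent at 3 T.
#' @param baselineFrames number of initial pre-contrast frames to average
#'   for the baseline signal; default taken from `dyn`.
#' @return a [ConcentrationSeries-class].
#' @export
signalToConcentration <- function(dyn, t1map, relaxivityR1 = 5.5,
                                  baselineFrames = dyn@baselineFrames) {
  stopifnot(is(dyn, "DynamicSeries"), is(t1map, "T1Map"))
  d <- dim(dyn@signal)
  if (!identical(dim(t1map@t1S), d[1:3]))
    stop("t1map grid does not match the dynamic series")
  baselineFrames <- as.integer(baselineFrames)
  if (baselineFrames < 1L || baselineFrames >= d[4])
    stop("baselineFrames must be in [1, nFrames)")
  nvox <- prod(d[1:3])
  sig <- matrix(dyn@signal, nrow = nvox)
  t10 <- as.vector(t1map@t1S)
  valid <- as.vector(t1map@validMask)
  a <- dyn@flipDeg * pi / 180
  trS <- dyn@trMs / 1000
  conc <- matrix(NA_real_, nrow = nvox, ncol = d[4])
  idx <- which(valid & is.finite(t10))
  if (length(idx)) {
    E10 <- exp(-trS / t10[idx])
    f10 <- sin(a) * (1 - E10) / (1 - E10 * cos(a))
    s0 <- rowMeans(sig[idx, seq_len(baselineFrames), drop = FALSE])
    m0 <- s0 / f10
    # invert S = M0 sin(a)(1-E1)/(1-E1 cos(a)) frame by frame
    sn <- sig[idx, , drop = FALSE] / (m0 * sin(a))
    E1 <- (1 - sn) / (1 - sn * cos(a))
    E1[E1 <= 0 | E1 >= 1] <- NA_real_
    r1t <- -log(E1) / trS          # 1/T1(t), s^-1
    conc[idx, ] <- (r1t - 1 / t10[idx]) / relaxivityR1
  }
  new("ConcentrationSeries", cMM = array(conc, d),
      timesMin = dyn@timesMin, relaxivityR1 = relaxivityR1,
      baselineFrames = baselineFrames)
}
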