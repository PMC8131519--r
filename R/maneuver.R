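#' Create a maneuver profile
#'
#' Defines the slow physiological time course imposed on the phantom's
#' complex shear modulus: a stiffness multiplier m(t) that is exactly 1 at
#' baseline, shows a calibrated early overshoot after maneuver onset, ramps
#' to a plateau while the maneuver is held, shows a second calibrated
#' overshoot after release, and relaxes exponentially back to baseline; and a
#' loss angle phi(t) that is reduced by a constant percentage while the
#' maneuver is held, with smooth transitions.
#'
#' Amplitude/delay defaults are group-mean in vivo values; shape parameters
#' (bump widths, plateau, recovery constant) are simulator choices discussed
#' in the vignette. The early bump's leading tail extends a few seconds
#' before onset, emulating the preparatory breath-hold that precedes the
#' maneuver; a smoothstep window `leadIn` seconds before onset zeroes the far
#' tail so the baseline is exactly 1.
#'
#' @param baselineGstar baseline |G*| in Pa.
#' @param baselinePhi baseline loss angle in rad.
#' @param onset,release maneuver onset and release times in seconds.
#' @param earlyOvershootPct,earlyDelay early overshoot amplitude in percent
#'   above baseline and delay after onset in seconds.
#' @param lateOvershootPct,lateDelay post-release overshoot amplitude and
#'   delay.
#' @param plateauRampPct plateau reached at release, percent above baseline.
#' @param rampDelay seconds after onset before the plateau ramp engages,
#'   producing the short drop between the early overshoot and the climb.
#' @param phiDipPct relative loss-angle change while the maneuver is held, in
#'   percent (negative = dip).
#' @param recoveryTau recovery time constant in seconds.
#' @param earlySigma,lateSigma Gaussian bump widths in seconds.
#' @param leadIn,leadWidth window start (s before onset) and width (s) for
#'   the early bump's leading tail.
#' @param transitionWidth loss-angle smoothstep width in seconds.
#' @return a [ManeuverProfile-class] object.
#' @examples
#' prof <- maneuverProfile()
#' fns <- maneuverFunctions(prof)
#' fns$m(10)                       # exactly 1 at baseline
#' fns$m(prof@onset + 2.4)         # 1.067 at the programmed early peak
#' @export
maneuverProfile <- function(baselineGstar = 1370,
                            baselinePhi = 0.800,
                            onset = 30,
                            release = 50,
                            earlyOvershootPct = 6.7,
                            earlyDelay = 2.4,
                            lateOvershootPct = 7.4,
                            lateDelay = 5.5,
                            plateauRampPct = 2.5,
                            rampDelay = 8,
                            phiDipPct = -2.1,
                            recoveryTau = 8,
                            earlySigma = 3.2,
                            lateSigma = 3.5,
                            leadIn = 9,
                            leadWidth = 3,
                            transitionWidth = 2.5) {
  new("ManeuverProfile",
      baselineGstar = baselineGstar, baselinePhi = baselinePhi,
      onset = onset, release = release,
      earlyOvershootPct = earlyOvershootPct, earlyDelay = earlyDelay,
      lateOvershootPct = lateOvershootPct, lateDelay = lateDelay,
      plateauRampPct = plateauRampPct, rampDelay = rampDelay,
      phiDipPct = phiDipPct,
      recoveryTau = recoveryTau, earlySigma = earlySigma,
      lateSigma = lateSigma, leadIn = leadIn, leadWidth = leadWidth,
      transitionWidth = transitionWidth)
}

## calibrate bump amplitudes/centres so the programmed peaks land exactly at
## (onset + earlyDelay, 1 + earlyOvershootPct/100) and the post-release
## maximum at (release + lateDelay, 1 + lateOvershootPct/100), despite the
## underlying ramp and recovery.
.calibrateManeuver <- function(p) {
  on <- p@onset; rel <- p@release
  a1 <- p@earlyOvershootPct / 100; a2 <- p@lateOvershootPct / 100
  ramp <- p@plateauRampPct / 100
  winStart <- on - p@leadIn
  rampOn <- on + min(p@rampDelay, 0.5 * (rel - on))
  R <- function(t) ifelse(t < rel,
                          ramp * sstep((t - rampOn) / (rel - rampOn)),
                          ramp * exp(-pmax(t - rel, 0) / p@recoveryTau))
  mk <- function(a1c, c1, a2c, c2) function(t)
    1 + a1c * exp(-(t - c1)^2 / (2 * p@earlySigma^2)) *
          sstep((t - winStart) / p@leadWidth) +
      R(t) +
      a2c * exp(-(t - c2)^2 / (2 * p@lateSigma^2))
  a1c <- a1; c1 <- on + p@earlyDelay
  a2c <- a2; c2 <- rel + p@lateDelay
  tg1 <- seq(on + 1e-3, on + max(10, 2 * p@earlyDelay), by = 0.002)
  tg2 <- seq(rel + 1e-3, rel + max(15, 2 * p@lateDelay), by = 0.002)
  for (it in 1:80) {
    m <- mk(a1c, c1, a2c, c2)
    v <- m(tg1); i <- which.max(v)
    c1 <- c1 + (on + p@earlyDelay - tg1[i])
    if (v[i] > 1) a1c <- a1c * a1 / (v[i] - 1)
    v <- m(tg2); i <- which.max(v)
    c2 <- c2 + (rel + p@lateDelay - tg2[i])
    if (v[i] > 1) a2c <- a2c * a2 / (v[i] - 1)
  }
  list(m = mk(a1c, c1, a2c, c2),
       pars = c(a1c = a1c, c1 = c1, a2c = a2c, c2 = c2))
}

#' Build the maneuver time-course functions
#'
#' Returns vectorized callables m(t) (stiffness multiplier, dimensionless)
#' and phi(t) (loss angle, rad). The bump amplitudes and centres are
#' calibrated numerically at construction so that the maximum of m over
#' (onset, onset+10] is exactly `1 + earlyOvershootPct/100`, attained
#' `earlyDelay` seconds after onset, and correspondingly for the post-release
#' overshoot.
#'
#' @param profile a [ManeuverProfile-class].
#' @return list with elements `m` and `phi`, both functions of time (s).
#' @export
maneuverFunctions <- function(profile) {
  validObject(profile)
  cal <- .calibrateManeuver(profile)
  on <- profile@onset; rel <- profile@release
  tw <- profile@transitionWidth
  phi0 <- profile@baselinePhi; dip <- profile@phiDipPct / 100
  phiFun <- function(t)
    phi0 * (1 + dip * sstep((t - on) / tw) * (1 - sstep((t - rel) / tw)))
  list(m = cal$m, phi = phiFun)
}

setMethod("show", "ManeuverProfile", function(object) {
  cat("ManeuverProfile\n")
  cat(sprintf("  baseline |G*| %.0f Pa, phi %.3f rad\n",
              object@baselineGstar, object@baselinePhi))
  cat(sprintf("  maneuver %g-%g s; overshoots %.1f%% @ +%.1f s (onset), %.1f%% @ +%.1f s (release)\n",
              object@onset, object@release,
              object@earlyOvershootPct, object@earlyDelay,
              object@lateOvershootPct, object@lateDelay))
  cat(sprintf("  plateau %.1f%%, phi dip %.1f%%, recovery tau %.1f s\n",
              object@plateauRampPct, object@phiDipPct, object@recoveryTau))
})
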