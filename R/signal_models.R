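## Pure forward signal models for the supported file collections.  These are
## used both by the digital-phantom generator and as oracles for the
## voxelwise fitters.  All functions operate elementwise on scalars or
## arrays; flip angles are taken in degrees at the interface (the metadata
## convention) and converted to radians internally.

.deg2rad <- function(x) x * pi / 180

## as.complex() drops dim attributes of numeric arrays; keep them
.asComplexKeep <- function(x) {
    d <- dim(x)
    y <- as.complex(x)
    dim(y) <- d
    y
}

#' Tissue parameter set
#'
#' Ground-truth physical parameters of a voxel (or arrays of voxels).
#'
#' @param t1,t2,t2star Relaxation time constants in seconds
#'   (\code{t2 <= t1}, \code{t2star <= t2}).
#' @param m0 Equilibrium magnetization amplitude (arbitrary units, >= 0).
#' @param mtr_frac Magnetization-transfer signal drop fraction in [0, 1).
#' @param mtsat_delta Per-excitation saturation of the bound pool
#'   (dimensionless; typical white matter ~0.04).
#' @param chi Magnetic susceptibility in ppm (carried, not simulated).
#' @param b1_rel Actual/nominal flip-angle ratio (1 = ideal transmit field).
#' @return List of class \code{tissue_params}.
#' @export
tissueParams <- function(t1, t2, t2star, m0, mtr_frac = 0,
                         mtsat_delta = 0, chi = 0, b1_rel = 1) {
    if (any(t1 <= 0) || any(t2 <= 0) || any(t2star <= 0))
        stop("time constants must be positive")
    if (any(t2 > t1 + 1e-12))
        stop("T2 must not exceed T1")
    if (any(t2star > t2 + 1e-12))
        stop("T2* must not exceed T2")
    if (any(m0 < 0)) stop("M0 must be non-negative")
    if (any(mtr_frac < 0 | mtr_frac >= 1))
        stop("mtr_frac must lie in [0, 1)")
    structure(list(t1 = t1, t2 = t2, t2star = t2star, m0 = m0,
                   mtr_frac = mtr_frac, mtsat_delta = mtsat_delta,
                   chi = chi, b1_rel = b1_rel),
              class = "tissue_params")
}

#' Spoiled gradient-echo steady-state signal
#'
#' Ernst steady state of an RF-spoiled gradient echo:
#' \deqn{S = M_0 \sin(b_1\alpha)\,(1 - E_1)/(1 - E_1\cos(b_1\alpha)),\quad
#'       E_1 = e^{-TR/T_1}.}
#' With an echo time given, the signal is additionally weighted by
#' \eqn{e^{-TE/T_2^*}}.
#'
#' @param t A \code{\link{tissueParams}} object.
#' @param tr Repetition time of excitation, seconds.
#' @param flipDeg Nominal flip angle, degrees.
#' @param te Optional echo time, seconds.
#' @return Signal (same shape as the tissue arrays).
#' @export
spgrSignal <- function(t, tr, flipDeg, te = NULL) {
    if (any(tr <= 0)) stop("tr must be positive")
    if (any(flipDeg <= 0) || any(flipDeg >= 180))
        stop("flip angle must lie in (0, 180) degrees")
    a <- .deg2rad(flipDeg) * t$b1_rel
    e1 <- exp(-tr / t$t1)
    s <- t$m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
    if (!is.null(te)) s <- s * exp(-te / t$t2star)
    s
}

#' Inversion-recovery signal (signed)
#'
#' \deqn{S = M_0 (1 - 2 e^{-TI/T_1} + e^{-TR/T_1})}
#' The signed value is returned; magnitude reconstruction is applied
#' downstream where the acquisition stores magnitudes.
#'
#' @param t A \code{\link{tissueParams}} object.
#' @param ti Inversion time, seconds (0 < ti < tr).
#' @param tr Repetition time of preparation, seconds.
#' @return Signed signal.
#' @export
irSignal <- function(t, ti, tr) {
    if (any(ti <= 0) || any(ti >= tr)) stop("need 0 < ti < tr")
    t$m0 * (1 - 2 * exp(-ti / t$t1) + exp(-tr / t$t1))
}

#' Monoexponential decay signal
#'
#' \eqn{S = m_0 e^{-TE/t_c}}; serves multi-echo spin echo with
#' \eqn{t_c = T_2} and multi-echo gradient echo with \eqn{t_c = T_2^*}.
#'
#' @param m0 Amplitude at zero echo time.
#' @param tc Decay time constant, seconds (> 0).
#' @param te Echo time, seconds (>= 0).
#' @return Signal.
#' @export
monoexpSignal <- function(m0, tc, te) {
    if (any(tc <= 0)) stop("tc must be positive")
    if (any(te < 0)) stop("te must be non-negative")
    m0 * exp(-te / tc)
}

#' MP2RAGE protocol
#'
#' Timing of one magnetization-prepared dual-gradient-echo cycle.  The two
#' inversion times mark the start of each rapid gradient-echo block; the
#' blocks (of \code{nExc} excitations spaced \code{trExc}) must fit between
#' the inversion times and within the cycle.
#'
#' @param trPrep Full cycle repetition time (RepetitionTimePreparation), s.
#' @param trExc Excitation spacing within a block
#'   (RepetitionTimeExcitation), s.
#' @param ti Length-2 vector of inversion times, s (ti1 < ti2).
#' @param flipsDeg Length-2 vector of block flip angles, degrees.
#' @param nExc Excitations per block.
#' @param invEff Inversion efficiency in (0, 1]; default 0.96.
#' @return List of class \code{mp2rage_protocol}.
#' @export
mp2rageProtocol <- function(trPrep, trExc, ti, flipsDeg, nExc,
                            invEff = 0.96) {
    stopifnot(length(ti) == 2L, length(flipsDeg) == 2L)
    if (!(ti[1] < ti[2] && ti[2] < trPrep))
        stop("need ti1 < ti2 < trPrep")
    blk <- nExc * trExc
    if (ti[1] + blk > ti[2] + 1e-12 || ti[2] + blk > trPrep + 1e-12)
        stop("gradient-echo blocks do not fit within the cycle timing")
    if (invEff <= 0 || invEff > 1) stop("invEff must lie in (0, 1]")
    structure(list(trPrep = trPrep, trExc = trExc, ti = ti,
                   flipsDeg = flipsDeg, nExc = as.integer(nExc),
                   invEff = invEff),
              class = "mp2rage_protocol")
}

## affine maps mz' = a*mz + b on the normalized longitudinal magnetization;
## composition applies `first` then `second`
.affRelax <- function(dt, t1) list(a = exp(-dt / t1), b = 1 - exp(-dt / t1))
.affPulse <- function(cosA) list(a = cosA, b = 0)
.affCompose <- function(first, second)
    list(a = second$a * first$a, b = second$a * first$b + second$b)
.affApply <- function(f, mz) f$a * mz + f$b

#' MP2RAGE block signals via exact steady state
#'
#' Propagates the longitudinal magnetization through one cycle -- inversion
#' (\eqn{m_z \to -\eta\, m_z}), recovery to the first inversion time, first
#' gradient-echo block, recovery to the second inversion time, second block,
#' recovery to the end of the cycle.  Every stage is affine in \eqn{m_z}, so
#' the steady state is the exact fixed point of the composed affine map,
#' \eqn{m_z^* = B/(1-A)}.  The returned complex signals are read at the
#' central excitation of each block, \eqn{S_i \propto M_0 \sin(b_1\alpha_i)
#' m_z}, with the inversion sign carried in the phase.
#'
#' @param t A \code{\link{tissueParams}} object (vectorized over voxels).
#' @param p A \code{\link{mp2rageProtocol}}.
#' @return List with complex elements \code{s1}, \code{s2}.
#' @export
mp2rageBlockSignals <- function(t, p) {
    stopifnot(inherits(p, "mp2rage_protocol"))
    t1 <- t$t1
    a1 <- .deg2rad(p$flipsDeg[1]) * t$b1_rel
    a2 <- .deg2rad(p$flipsDeg[2]) * t$b1_rel
    n <- p$nExc
    kc <- ceiling(n / 2)           # central excitation (1-based)
    blk <- n * p$trExc
    ## elementary stages
    inv <- list(a = -p$invEff + 0 * t1, b = 0 * t1)
    rec1 <- .affRelax(p$ti[1], t1)
    rec2 <- .affRelax(p$ti[2] - p$ti[1] - blk, t1)
    rec3 <- .affRelax(p$trPrep - p$ti[2] - blk, t1)
    unit <- function(cosA) .affCompose(.affPulse(cosA), .affRelax(p$trExc, t1))
    pw <- function(f, k) {            # f composed k times
        out <- list(a = 1 + 0 * t1, b = 0 * t1)
        while (k > 0) { out <- .affCompose(out, f); k <- k - 1 }
        out
    }
    u1 <- unit(cos(a1)); u2 <- unit(cos(a2))
    blk1 <- pw(u1, n); blk2 <- pw(u2, n)
    cycle <- Reduce(.affCompose, list(inv, rec1, blk1, rec2, blk2, rec3))
    A <- cycle$a; B <- cycle$b
    if (any(abs(1 - A) < 1e-12))
        stop("non-convergent protocol: composed cycle map has unit gain")
    mzss <- B / (1 - A)
    ## propagate to just before the central excitation of each block
    pre1 <- Reduce(.affCompose, list(inv, rec1, pw(u1, kc - 1)))
    mz1 <- .affApply(pre1, mzss)
    pre2 <- Reduce(.affCompose, list(inv, rec1, blk1, rec2, pw(u2, kc - 1)))
    mz2 <- .affApply(pre2, mzss)
    list(s1 = .asComplexKeep(t$m0 * sin(a1) * mz1),
         s2 = .asComplexKeep(t$m0 * sin(a2) * mz2))
}

#' MP2RAGE uniform (UNI) combination
#'
#' \deqn{UNI = \mathrm{Re}(S_1 \bar S_2) / (|S_1|^2 + |S_2|^2) \in
#'   [-0.5, 0.5].}
#' Invariant under multiplication of both inputs by any nonzero complex
#' factor, hence insensitive to receive field and M0.  Voxels where both
#' signals vanish yield \code{NaN}.
#'
#' @param s1,s2 Complex signals (scalars or arrays).
#' @return Real combination in [-0.5, 0.5].
#' @export
mp2rageUni <- function(s1, s2) {
    s1 <- .asComplexKeep(s1); s2 <- .asComplexKeep(s2)
    den <- Mod(s1)^2 + Mod(s2)^2
    out <- Re(s1 * Conj(s2)) / den
    out[den == 0] <- NaN
    out
}

#' Double-angle B1+ mapping signals
#'
#' Long-TR limit (no T1 weighting): \eqn{S_1 = M_0\sin(b_1\alpha)},
#' \eqn{S_2 = M_0\sin(2 b_1\alpha)}.
#'
#' @param t A \code{\link{tissueParams}} object.
#' @param nominalDeg Nominal flip angle of the first acquisition, degrees.
#' @return List with elements \code{s1}, \code{s2}.
#' @export
damSignals <- function(t, nominalDeg) {
    a <- .deg2rad(nominalDeg) * t$b1_rel
    list(s1 = t$m0 * sin(a), s2 = t$m0 * sin(2 * a))
}

#' Actual-flip-angle-imaging protocol
#' @param tr1,tr2 The two interleaved repetition times, s (tr2 > tr1).
#' @param flipDeg Nominal flip angle, degrees.
#' @return List of class \code{afi_protocol} with \code{n = tr2/tr1}.
#' @export
afiProtocol <- function(tr1, tr2, flipDeg) {
    if (!(tr1 > 0 && tr2 > tr1)) stop("need tr2 > tr1 > 0")
    structure(list(tr1 = tr1, tr2 = tr2, flipDeg = flipDeg, n = tr2 / tr1),
              class = "afi_protocol")
}

#' Actual-flip-angle-imaging signal ratio
#'
#' Short-TR ideal-spoiling approximation:
#' \deqn{r = S_2/S_1 = (1 + n\cos(b_1\alpha)) / (n + \cos(b_1\alpha)),\quad
#'       n = TR_2/TR_1.}
#' A warning is raised when the repetition times are not short relative to
#' T1 (the regime the approximation assumes).
#'
#' @param t A \code{\link{tissueParams}} object.
#' @param p An \code{\link{afiProtocol}}.
#' @return The ratio r.
#' @export
afiRatio <- function(t, p) {
    stopifnot(inherits(p, "afi_protocol"))
    if (any(p$tr2 > 0.3 * t$t1))
        warning("AFI repetition times are not small relative to T1; the ",
                "short-TR approximation may be inaccurate")
    ca <- cos(.deg2rad(p$flipDeg) * t$b1_rel)
    (1 + p$n * ca) / (p$n + ca)
}

#' Magnetization-transfer-saturation protocol (three arms)
#'
#' @param flipMT,flipPD,flipT1 Flip angles of the MT-weighted, PD-weighted
#'   and T1-weighted arms, degrees (\code{flipT1 > flipPD}; small angles).
#' @param trMT,trPD,trT1 Repetition times of the three arms, s.
#' @return List of class \code{mts_protocol}; arm order MTw, PDw, T1w.
#' @export
mtsProtocol <- function(flipMT, trMT, flipPD, trPD, flipT1, trT1) {
    if (!(flipT1 > flipPD)) stop("need flipT1 > flipPD")
    if (any(c(flipMT, flipPD, flipT1) > 25))
        warning("flip angles above ~25 degrees strain the small-angle ",
                "approximation used by the MTsat model")
    structure(list(flipMT = flipMT, trMT = trMT, flipPD = flipPD,
                   trPD = trPD, flipT1 = flipT1, trT1 = trT1),
              class = "mts_protocol")
}

#' Magnetization-transfer-saturation forward signals
#'
#' Rational small-angle steady state.  For the non-MT arms
#' \deqn{S = A\,\alpha\, R_1 TR / (\alpha^2/2 + R_1 TR)} with
#' \eqn{A = M_0}, \eqn{R_1 = 1/T_1}, \eqn{\alpha} in radians; for the
#' MT-weighted arm the per-cycle saturation \eqn{\delta} adds in the
#' denominator.
#'
#' @param t A \code{\link{tissueParams}} object (uses \code{m0}, \code{t1},
#'   \code{mtsat_delta}, \code{b1_rel}).
#' @param p An \code{\link{mtsProtocol}}.
#' @return List with elements \code{sMT}, \code{sPD}, \code{sT1}.
#' @export
mtsSignals <- function(t, p) {
    stopifnot(inherits(p, "mts_protocol"))
    r1 <- 1 / t$t1
    arm <- function(flipDeg, tr, delta = 0) {
        a <- .deg2rad(flipDeg) * t$b1_rel
        t$m0 * a * (r1 * tr) / (a^2 / 2 + delta + r1 * tr)
    }
    list(sMT = arm(p$flipMT, p$trMT, t$mtsat_delta),
         sPD = arm(p$flipPD, p$trPD),
         sT1 = arm(p$flipT1, p$trT1))
}
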