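## Voxelwise inverse problems: turn file collections (or bare arrays plus
## protocol records) into quantitative parameter maps.  All fitters are
## deterministic and vectorized across voxels; voxels that cannot be fitted
## are NaN in the output maps and excluded from the mask.

#' FitResult: output of a voxelwise fitter
#'
#' @slot maps Named list of 3-D arrays, keyed by registered map suffix;
#'   unfittable voxels are \code{NaN}.
#' @slot units Named character vector: canonical units per map.
#' @slot mask Logical array of fitted voxels.
#' @slot diagnostics List: \code{n_masked}, \code{n_clipped} and solver
#'   notes.
#' @export
setClass("FitResult",
         representation(maps = "list", units = "character",
                        mask = "array", diagnostics = "list"),
         validity = function(object) {
             bad <- setdiff(names(object@maps), listMapSuffixes())
             if (length(bad))
                 return(paste0("unregistered map suffix: ",
                               paste(bad, collapse = ", ")))
             TRUE
         })

#' @describeIn FitResult Compact display.
#' @param object A \code{FitResult}.
#' @export
setMethod("show", "FitResult", function(object) {
    cat("FitResult with map(s): ",
        paste(sprintf("%s [%s]", names(object@maps), object@units),
              collapse = ", "), "\n", sep = "")
    cat("  voxels fitted: ", sum(object@mask), "/", length(object@mask),
        "\n", sep = "")
})

#' Accessors for FitResult
#' @param x A \code{FitResult}.
#' @param mapSuffix Which map to extract; default the first.
#' @return \code{fittedMap}: the named 3-D array; \code{fitMask}: logical
#'   array of fitted voxels; \code{fitDiagnostics}: diagnostics list.
#' @export
fittedMap <- function(x, mapSuffix = names(x@maps)[1L]) {
    m <- x@maps[[mapSuffix]]
    if (is.null(m)) stop("no such map in this fit: ", mapSuffix)
    m
}

#' @rdname fittedMap
#' @export
fitMask <- function(x) x@mask

#' @rdname fittedMap
#' @export
fitDiagnostics <- function(x) x@diagnostics

.newFitResult <- function(maps, mask, diagnostics = list()) {
    diagnostics$n_masked <- sum(!mask)
    if (is.null(diagnostics$n_clipped)) diagnostics$n_clipped <- 0L
    units <- vapply(names(maps), unitsForMap, "")
    methods::new("FitResult", maps = maps, units = units,
                 mask = as.array(mask), diagnostics = diagnostics)
}

## accept an image_volume, an array, or a list of either; return matrix of
## voxel values (nvox x nvol) plus the original dim
.stackVolumes <- function(volumes) {
    if (inherits(volumes, "image_volume") || is.numeric(volumes))
        volumes <- list(volumes)
    arrs <- lapply(volumes, function(v)
        if (inherits(v, "image_volume")) v$voxels else v)
    d <- dim(as.array(arrs[[1L]]))
    for (a in arrs)
        if (!identical(dim(as.array(a)), d))
            stop("input volumes have mismatched shapes")
    list(mat = vapply(arrs, function(a) as.vector(a),
                      numeric(prod(d))),
         dim = d)
}

.shape <- function(v, d) { out <- v; dim(out) <- d; out }

#' Variable-flip-angle T1 fitting
#'
#' Linearized least squares on the spoiled gradient-echo steady state: with
#' \eqn{y = S/\sin\alpha} and \eqn{x = S/\tan\alpha}, voxels obey
#' \eqn{y = E_1 x + M_0(1-E_1)}, so \eqn{T_1 = -TR/\ln(\mathrm{slope})} and
#' \eqn{M_0 = \mathrm{intercept}/(1-\mathrm{slope})}.  With a transmit-field
#' map given, the nominal angles are scaled voxelwise by \code{b1map/100}.
#'
#' @param signals List of 3-D arrays or \code{image_volume}s, one per flip
#'   angle.
#' @param flipsDeg Nominal flip angles, degrees (>= 2 distinct values).
#' @param tr Excitation repetition time, seconds.
#' @param b1map Optional transmit-field map in relative percent
#'   (100 = nominal).
#' @return A \code{\link{FitResult}} with \code{T1map} (s) and
#'   \code{M0map}.
#' @export
fitVFA <- function(signals, flipsDeg, tr, b1map = NULL) {
    if (length(unique(flipsDeg)) < 2L)
        stop("variable-flip-angle fitting needs at least 2 distinct flip ",
             "angles")
    st <- .stackVolumes(signals)
    S <- st$mat
    if (length(flipsDeg) != ncol(S))
        stop("length(flipsDeg) must match the number of volumes")
    k <- ncol(S)
    a <- matrix(.deg2rad(flipsDeg), nrow(S), k, byrow = TRUE)
    if (!is.null(b1map)) {
        b1 <- as.vector(if (inherits(b1map, "image_volume")) b1map$voxels
                        else b1map) / 100
        if (length(b1) != nrow(S)) stop("b1map shape mismatch")
        a <- a * b1
    }
    y <- S / sin(a); x <- S / tan(a)
    sx <- rowSums(x); sy <- rowSums(y)
    sxx <- rowSums(x * x); sxy <- rowSums(x * y)
    den <- k * sxx - sx^2
    slope <- (k * sxy - sx * sy) / den
    icpt <- (sy - slope * sx) / k
    ok <- is.finite(slope) & slope > 0 & slope < 1
    t1 <- rep(NaN, nrow(S)); m0 <- rep(NaN, nrow(S))
    t1[ok] <- -tr / log(slope[ok])
    m0[ok] <- icpt[ok] / (1 - slope[ok])
    mask <- ok & is.finite(t1) & t1 > 0
    t1[!mask] <- NaN; m0[!mask] <- NaN
    .newFitResult(list(T1map = .shape(t1, st$dim),
                       M0map = .shape(m0, st$dim)),
                  .shape(mask, st$dim))
}

## one-dimensional least squares in T1 for the three-parameter IR model
## S = a + b exp(-ti/T1): a, b are linear given T1, so profile them out and
## minimize over T1 by grid search plus golden-section refinement.
.irProfileRSS <- function(s, tis, t1) {
    e <- exp(-tis / t1)
    X <- cbind(1, e)
    fit <- stats::lm.fit(X, s)
    sum(fit$residuals^2)
}

.irFitSigned <- function(s, tis, grid) {
    rss <- vapply(grid, function(t1) .irProfileRSS(s, tis, t1), 0)
    i <- which.min(rss)
    lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
    opt <- stats::optimize(function(t1) .irProfileRSS(s, tis, t1),
                           lower = lo, upper = hi, tol = 1e-12)
    t1 <- opt$minimum
    e <- exp(-tis / t1)
    cf <- stats::lm.fit(cbind(1, e), s)$coefficients
    list(t1 = t1, a = cf[1L], b = cf[2L], rss = opt$objective)
}

#' Inversion-recovery T1 fitting
#'
#' Per voxel, least squares of the three-parameter model
#' \eqn{S(TI) = a + b\,e^{-TI/T_1}} (signed).  The amplitudes enter
#' linearly, so they are profiled out and the minimization is a robust 1-D
#' search over \eqn{T_1}.  For magnitude data the polarity is restored by
#' trying every sign-flip position along the sorted inversion times and
#' keeping the lowest-residual fit.  Voxels with no decay information
#' (constant signal) or a non-physical fit are masked.
#'
#' @param signals List of 3-D arrays or \code{image_volume}s, one per
#'   inversion time.
#' @param tis Inversion times, seconds (>= 3).
#' @param tr Repetition time of preparation, seconds (bounds the T1 search).
#' @param magnitude Are the data magnitudes (polarity lost)?
#' @return A \code{\link{FitResult}} with \code{T1map} (s).
#' @export
fitIR <- function(signals, tis, tr, magnitude = FALSE) {
    if (length(tis) < 3L)
        stop("inversion-recovery fitting needs at least 3 inversion times")
    st <- .stackVolumes(signals)
    ord <- order(tis)
    tis <- tis[ord]
    S <- st$mat[, ord, drop = FALSE]
    grid <- exp(seq(log(0.02), log(2 * tr), length.out = 60L))
    nv <- nrow(S)
    t1 <- rep(NaN, nv)
    scale <- pmax(apply(abs(S), 1L, max), .Machine$double.eps)
    flat <- apply(S, 1L, function(s) diff(range(s))) < 1e-9 * scale
    ## identical signal vectors are fitted once (piecewise-constant phantoms)
    key <- apply(S, 1L, paste, collapse = ",")
    firsts <- which(!duplicated(key) & !flat)
    fitted <- new.env(parent = emptyenv())
    for (i in firsts) {
        s <- S[i, ]
        if (magnitude) {
            best <- NULL
            for (j in 0:length(tis)) {
                sj <- s
                if (j > 0) sj[seq_len(j)] <- -sj[seq_len(j)]
                f <- .irFitSigned(sj, tis, grid)
                if (is.null(best) || f$rss < best$rss) best <- f
            }
        } else {
            best <- .irFitSigned(s, tis, grid)
        }
        ok <- is.finite(best$t1) && best$t1 > 0 && is.finite(best$b) &&
            best$b < 0   # recovery: negative exponential amplitude
        assign(key[i], if (ok) best$t1 else NaN, envir = fitted)
    }
    for (i in seq_len(nv)) {
        if (flat[i]) next
        t1[i] <- get(key[i], envir = fitted)
    }
    mask <- is.finite(t1)
    .newFitResult(list(T1map = .shape(t1, st$dim)), .shape(mask, st$dim))
}

#' Monoexponential decay fitting (T2 / T2*)
#'
#' Weighted log-linear least squares of \eqn{\ln S = \ln M_0 - TE/t_c} with
#' weights proportional to the signal, countering the heteroscedasticity
#' introduced by the log transform.  Exact on noiseless exponentials.
#'
#' @param signals List of 3-D arrays or \code{image_volume}s, one per echo.
#' @param tes Echo times, seconds (>= 2, distinct).
#' @param mapSuffix \code{"T2map"} (spin echo) or \code{"T2starmap"}
#'   (gradient echo).
#' @return A \code{\link{FitResult}} with the decay-constant map (s) and
#'   \code{M0map}.  Voxels with any non-positive echo signal are masked.
#' @export
fitMonoexp <- function(signals, tes, mapSuffix = c("T2map", "T2starmap")) {
    mapSuffix <- match.arg(mapSuffix)
    if (length(tes) < 2L || anyDuplicated(tes))
        stop("monoexponential fitting needs >= 2 distinct echo times")
    st <- .stackVolumes(signals)
    S <- st$mat
    if (length(tes) != ncol(S))
        stop("length(tes) must match the number of volumes")
    pos <- rowSums(S <= 0) == 0L
    y <- log(pmax(S, .Machine$double.xmin))
    w <- S
    x <- matrix(tes, nrow(S), length(tes), byrow = TRUE)
    sw <- rowSums(w)
    xb <- rowSums(w * x) / sw
    yb <- rowSums(w * y) / sw
    sxx <- rowSums(w * (x - xb)^2)
    sxy <- rowSums(w * (x - xb) * (y - yb))
    slope <- sxy / sxx
    tc <- -1 / slope
    m0 <- exp(yb - slope * xb)
    mask <- pos & is.finite(tc) & tc > 0
    tc[!mask] <- NaN; m0[!mask] <- NaN
    maps <- list(.shape(tc, st$dim), M0map = .shape(m0, st$dim))
    names(maps)[1L] <- mapSuffix
    .newFitResult(maps, .shape(mask, st$dim))
}

#' Magnetization transfer ratio
#'
#' \eqn{MTR = 100\,(S_{off} - S_{on})/S_{off}} in percent.  Voxels with
#' non-positive off-resonance signal are masked.
#'
#' @param sOff,sOn 3-D arrays or \code{image_volume}s: the MT-off and MT-on
#'   members of one collection.
#' @return A \code{\link{FitResult}} with \code{MTRmap} (%).
#' @export
computeMTR <- function(sOff, sOn) {
    st <- .stackVolumes(list(sOff, sOn))
    off <- st$mat[, 1L]; on <- st$mat[, 2L]
    mask <- off > 0
    mtr <- rep(NaN, length(off))
    mtr[mask] <- 100 * (off[mask] - on[mask]) / off[mask]
    sub <- sum(mtr[mask] < 0)
    .newFitResult(list(MTRmap = .shape(mtr, st$dim)), .shape(mask, st$dim),
                  diagnostics = list(n_negative = sub))
}

#' Magnetization transfer saturation (MTsat)
#'
#' Closed-form inversion of the rational small-angle steady state from the
#' three-arm protocol (MT-, PD- and T1-weighted).  Per voxel, with
#' \eqn{\alpha} in radians:
#' \deqn{R_1 = \tfrac12 (S_{T1}\alpha_{T1}/TR_{T1} -
#'   S_{PD}\alpha_{PD}/TR_{PD}) / (S_{PD}/\alpha_{PD} -
#'   S_{T1}/\alpha_{T1})}
#' \deqn{A = S_{PD} S_{T1} (TR_{PD}\alpha_{T1}/\alpha_{PD} -
#'   TR_{T1}\alpha_{PD}/\alpha_{T1}) / (S_{T1} TR_{PD} \alpha_{T1} -
#'   S_{PD} TR_{T1} \alpha_{PD})}
#' \deqn{\delta = (A\alpha_{MT}/S_{MT} - 1) R_1 TR_{MT} -
#'   \alpha_{MT}^2/2}
#' MTsat is reported as \eqn{100\,\delta} (percent-style convention for the
#' per-excitation saturation).
#'
#' @param sMT,sPD,sT1 3-D arrays or \code{image_volume}s of the three arms.
#' @param p An \code{\link{mtsProtocol}}.
#' @return A \code{\link{FitResult}} with \code{MTsat}, \code{R1map} (1/s)
#'   and \code{M0map}.
#' @export
computeMTsat <- function(sMT, sPD, sT1, p) {
    stopifnot(inherits(p, "mts_protocol"))
    st <- .stackVolumes(list(sMT, sPD, sT1))
    smt <- st$mat[, 1L]; spd <- st$mat[, 2L]; st1 <- st$mat[, 3L]
    aMT <- .deg2rad(p$flipMT); aPD <- .deg2rad(p$flipPD)
    aT1 <- .deg2rad(p$flipT1)
    if (abs(aT1 - aPD) < 1e-12)
        stop("degenerate protocol: T1- and PD-weighted arms share one flip ",
             "angle")
    denR1 <- spd / aPD - st1 / aT1
    denA <- st1 * p$trPD * aT1 - spd * p$trT1 * aPD
    ok <- is.finite(denR1) & is.finite(denA) &
        abs(denR1) > .Machine$double.eps & abs(denA) > .Machine$double.eps &
        smt > 0 & spd > 0 & st1 > 0
    r1 <- a <- delta <- rep(NaN, length(smt))
    r1[ok] <- 0.5 * (st1[ok] * aT1 / p$trT1 - spd[ok] * aPD / p$trPD) /
        denR1[ok]
    a[ok] <- spd[ok] * st1[ok] *
        (p$trPD * aT1 / aPD - p$trT1 * aPD / aT1) / denA[ok]
    delta[ok] <- (a[ok] * aMT / smt[ok] - 1) * r1[ok] * p$trMT - aMT^2 / 2
    mask <- ok & is.finite(delta) & is.finite(r1) & r1 > 0
    delta[!mask] <- NaN; r1[!mask] <- NaN; a[!mask] <- NaN
    .newFitResult(list(MTsat = .shape(100 * delta, st$dim),
                       R1map = .shape(r1, st$dim),
                       M0map = .shape(a, st$dim)),
                  .shape(mask, st$dim))
}

#' MP2RAGE T1 fitting via lookup inversion
#'
#' Builds the UNI(T1) lookup from the exact steady-state forward model over
#' a T1 grid, restricts it to its maximal monotonic sub-interval (with a
#' warning when the full range is not monotonic) and inverts each voxel's
#' UNI value by linear interpolation.  Voxels outside the lookup span are
#' masked.  Thanks to the scale invariance of the UNI combination the result
#' is unaffected by any common complex factor on the inputs.
#'
#' @param s1,s2 Complex 3-D arrays (signals of the two gradient-echo
#'   blocks), or \code{NULL} when \code{uni} is given directly.
#' @param p An \code{\link{mp2rageProtocol}}.
#' @param uni Optional precombined UNI volume in [-0.5, 0.5].
#' @param t1Range T1 grid range, seconds; default 0.05--5.
#' @param t1Step Grid step, seconds; default 0.001 (1 ms).
#' @return A \code{\link{FitResult}} with \code{T1map} (s).
#' @export
fitMP2RAGE <- function(s1 = NULL, s2 = NULL, p, uni = NULL,
                       t1Range = c(0.05, 5), t1Step = 0.001) {
    stopifnot(inherits(p, "mp2rage_protocol"))
    if (is.null(uni)) {
        if (is.null(s1) || is.null(s2))
            stop("provide either both block signals or a precombined UNI ",
                 "volume")
        if (inherits(s1, "image_volume")) s1 <- s1$voxels
        if (inherits(s2, "image_volume")) s2 <- s2$voxels
        uni <- mp2rageUni(s1, s2)
    } else if (inherits(uni, "image_volume")) uni <- uni$voxels
    d <- dim(uni)
    grid <- seq(t1Range[1L], t1Range[2L], by = t1Step)
    tp <- tissueParams(t1 = grid, t2 = grid, t2star = grid, m0 = 1)
    sg <- mp2rageBlockSignals(tp, p)
    lut <- mp2rageUni(sg$s1, sg$s2)
    ## maximal strictly monotonic run of the lookup
    ds <- sign(diff(lut))
    runs <- rle(ds)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    iBest <- which.max(ifelse(runs$values == 0, 0L, runs$lengths))
    lo <- starts[iBest]; hi <- ends[iBest] + 1L
    if (hi - lo + 1L < length(grid))
        warning("UNI lookup is not monotonic over the full T1 range; ",
                "restricted to T1 in [", signif(grid[lo], 4), ", ",
                signif(grid[hi], 4), "] s")
    lutM <- lut[lo:hi]; gridM <- grid[lo:hi]
    if (lutM[1L] > lutM[length(lutM)]) {   # approx needs ascending x
        lutM <- rev(lutM); gridM <- rev(gridM)
    }
    v <- as.vector(uni)
    t1 <- stats::approx(lutM, gridM, xout = v, ties = "ordered",
                        rule = 1)$y
    mask <- !is.na(t1)
    t1[!mask] <- NaN
    .newFitResult(list(T1map = .shape(t1, d)), .shape(mask, d))
}

#' Double-angle B1+ fitting
#'
#' From the double-angle identity \eqn{S_2/(2 S_1) = \cos(b_1\alpha)}:
#' \deqn{TB1 = 100\,\arccos(\mathrm{clamp}(S_2/(2S_1), -1, 1)) /
#'   \alpha_{nom}.}
#' Ratios pushed outside [-1, 1] by noise are clamped (and counted in the
#' diagnostics) rather than masked, keeping the map dense.
#'
#' @param s1,s2 3-D arrays or \code{image_volume}s at the nominal and double
#'   flip angle.
#' @param nominalDeg Nominal flip angle of the first acquisition, degrees;
#'   the second must be its double (checked by the collection-level driver).
#' @return A \code{\link{FitResult}} with \code{TB1map} (relative %, 100 =
#'   nominal).
#' @export
fitDAM <- function(s1, s2, nominalDeg) {
    st <- .stackVolumes(list(s1, s2))
    v1 <- st$mat[, 1L]; v2 <- st$mat[, 2L]
    mask <- v1 > 0
    ratio <- v2 / (2 * v1)
    nClip <- sum(mask & (ratio < -1 | ratio > 1))
    ratio <- pmin(pmax(ratio, -1), 1)
    tb1 <- rep(NaN, length(v1))
    tb1[mask] <- 100 * acos(ratio[mask]) / .deg2rad(nominalDeg)
    .newFitResult(list(TB1map = .shape(tb1, st$dim)), .shape(mask, st$dim),
                  diagnostics = list(n_clipped = nClip))
}

#' Actual-flip-angle-imaging B1+ fitting
#'
#' Inverts the short-TR dual-TR steady-state ratio: with \eqn{r = S_2/S_1}
#' and \eqn{n = TR_2/TR_1}, \eqn{\cos\alpha = (rn - 1)/(n - r)} and
#' \eqn{TB1 = 100\,\alpha/\alpha_{nom}}.  Voxels with \eqn{|\cos\alpha| >
#' 1} or degenerate ratio \eqn{r \approx n} are masked.
#'
#' @param s1,s2 3-D arrays or \code{image_volume}s acquired at TR1 and TR2.
#' @param p An \code{\link{afiProtocol}} (must have \code{n > 1}).
#' @param nominalDeg Nominal flip angle, degrees; defaults to the protocol's.
#' @return A \code{\link{FitResult}} with \code{TB1map} (relative %).
#' @export
fitAFI <- function(s1, s2, p, nominalDeg = p$flipDeg) {
    stopifnot(inherits(p, "afi_protocol"))
    if (p$n <= 1) stop("AFI needs n = tr2/tr1 > 1")
    st <- .stackVolumes(list(s1, s2))
    v1 <- st$mat[, 1L]; v2 <- st$mat[, 2L]
    r <- v2 / v1
    ok <- v1 > 0 & is.finite(r) & abs(p$n - r) > 1e-9
    ca <- (r * p$n - 1) / (p$n - r)
    ok <- ok & abs(ca) <= 1
    tb1 <- rep(NaN, length(v1))
    tb1[ok] <- 100 * acos(ca[ok]) / .deg2rad(nominalDeg)
    .newFitResult(list(TB1map = .shape(tb1, st$dim)), .shape(ok, st$dim))
}
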