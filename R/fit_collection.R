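## High-level driver: read a file collection's volumes and metadata, run the
## matching voxelwise fitter, and package the result as QuantitativeMap
## objects with full provenance.

.memberVolumes <- function(collection)
    lapply(collection@members, function(m) readVolume(m$path)$voxels)

.constMeta <- function(collection, fields) {
    out <- list()
    for (f in fields) {
        v <- collection@members[[1L]]$sidecar$values[[f]]
        if (!is.null(v)) out[[f]] <- v
    }
    out
}

#' Fit a file collection to its quantitative maps
#'
#' Dispatches on the collection suffix to the matching voxelwise fitter,
#' reading acquisition parameters from the resolved sidecar metadata (never
#' from filenames).  Supported suffixes: VFA, IRT1, MESE, MEGRE, MTR, MTS,
#' MP2RAGE, TB1DAM, TB1AFI.  The remaining registered suffixes are
#' schema-only (validation support without fitting).
#'
#' @param collection A \code{FileCollection} with resolved sidecars.
#' @param b1map Optional transmit-field map (relative percent) for
#'   flip-angle correction where the model supports it (VFA).
#' @return A list with elements \code{fit} (the \code{\link{FitResult}})
#'   and \code{maps} (list of \code{\link{QuantitativeMap}}s carrying
#'   provenance).
#' @export
fitCollection <- function(collection, b1map = NULL) {
    stopifnot(is(collection, "FileCollection"))
    suffix <- collection@suffix
    tab <- parameterTable(collection)
    vols <- .memberVolumes(collection)
    rels <- vapply(collection@members, function(m)
        if (!is.null(m$rel)) m$rel else m$path, "")
    fit <- switch(suffix,
    VFA = {
        ord <- order(as.integer(tab$flip))
        tr <- .constMeta(collection, "RepetitionTimeExcitation")[[1L]]
        if (is.null(tr)) stop("VFA fitting needs RepetitionTimeExcitation")
        fitVFA(vols[ord], tab$FlipAngle[ord], tr, b1map = b1map)
    },
    IRT1 = {
        ord <- order(as.integer(tab$inv))
        tr <- .constMeta(collection, "RepetitionTimePreparation")[[1L]]
        if (is.null(tr)) tr <- max(tab$InversionTime) * 2.5
        fitIR(vols[ord], tab$InversionTime[ord], tr, magnitude = TRUE)
    },
    MESE = {
        ord <- order(as.integer(tab$echo))
        fitMonoexp(vols[ord], tab$EchoTime[ord], "T2map")
    },
    MEGRE = {
        ord <- order(as.integer(tab$echo))
        fitMonoexp(vols[ord], tab$EchoTime[ord], "T2starmap")
    },
    MTR = {
        iOff <- which(tab$mt == "off"); iOn <- which(tab$mt == "on")
        if (length(iOff) != 1L || length(iOn) != 1L)
            stop("MTR fitting needs exactly one mt-off and one mt-on member")
        computeMTR(vols[[iOff]], vols[[iOn]])
    },
    MTS = {
        iMT <- which(tab$MTState == "on")
        offs <- which(tab$MTState == "off")
        if (length(iMT) != 1L || length(offs) != 2L)
            stop("MTS fitting needs one MT-weighted and two reference arms")
        fa <- tab$FlipAngle[offs]
        iPD <- offs[which.min(fa)]; iT1 <- offs[which.max(fa)]
        trOf <- function(i) {
            v <- collection@members[[i]]$sidecar$values$RepetitionTimeExcitation
            if (is.null(v)) stop("MTS fitting needs RepetitionTimeExcitation")
            as.numeric(v)
        }
        p <- mtsProtocol(flipMT = tab$FlipAngle[iMT], trMT = trOf(iMT),
                         flipPD = tab$FlipAngle[iPD], trPD = trOf(iPD),
                         flipT1 = tab$FlipAngle[iT1], trT1 = trOf(iT1))
        computeMTsat(vols[[iMT]], vols[[iPD]], vols[[iT1]], p)
    },
    MP2RAGE = {
        pick <- function(inv, part)
            which(as.integer(tab$inv) == inv & tab$part == part)
        idx <- list(m1 = pick(1, "mag"), p1 = pick(1, "phase"),
                    m2 = pick(2, "mag"), p2 = pick(2, "phase"))
        if (any(vapply(idx, length, 0L) != 1L))
            stop("MP2RAGE fitting needs magnitude+phase pairs for both ",
                 "inversions")
        cst <- .constMeta(collection,
                          c("RepetitionTimePreparation",
                            "RepetitionTimeExcitation", "NumberShots"))
        tis <- vapply(1:2, function(i)
            tab$InversionTime[pick(i, "mag")], 0)
        flips <- vapply(1:2, function(i) {
            v <- collection@members[[pick(i, "mag")]]$sidecar$values$FlipAngle
            if (is.null(v)) stop("MP2RAGE fitting needs FlipAngle per ",
                                 "inversion")
            as.numeric(v)
        }, 0)
        if (is.null(cst$RepetitionTimePreparation) ||
            is.null(cst$RepetitionTimeExcitation))
            stop("MP2RAGE fitting needs RepetitionTimePreparation and ",
                 "RepetitionTimeExcitation")
        nExc <- if (!is.null(cst$NumberShots)) as.integer(cst$NumberShots)
                else 160L
        p <- mp2rageProtocol(trPrep = cst$RepetitionTimePreparation,
                             trExc = cst$RepetitionTimeExcitation,
                             ti = tis, flipsDeg = flips, nExc = nExc)
        s1 <- vols[[idx$m1]] * exp(1i * vols[[idx$p1]])
        s2 <- vols[[idx$m2]] * exp(1i * vols[[idx$p2]])
        fitMP2RAGE(s1, s2, p)
    },
    TB1DAM = {
        ord <- order(as.integer(tab$flip))
        fa <- tab$FlipAngle[ord]
        if (abs(fa[2L] - 2 * fa[1L]) > 1e-9)
            stop("double-angle fitting needs FlipAngle(flip-2) = ",
                 "2 x FlipAngle(flip-1); got ", fa[1L], " / ", fa[2L])
        fitDAM(vols[[ord[1L]]], vols[[ord[2L]]], nominalDeg = fa[1L])
    },
    TB1AFI = {
        ord <- order(as.integer(tab$flip))
        trs <- vapply(ord, function(i) {
            v <- collection@members[[i]]$sidecar$values$RepetitionTimeExcitation
            if (is.null(v)) stop("AFI fitting needs per-volume ",
                                 "RepetitionTimeExcitation")
            as.numeric(v)
        }, 0)
        p <- afiProtocol(tr1 = trs[1L], tr2 = trs[2L],
                         flipDeg = tab$FlipAngle[ord][1L])
        fitAFI(vols[[ord[1L]]], vols[[ord[2L]]], p)
    },
    stop("no fitter is implemented for suffix '", suffix,
         "' (schema-only collection)"))
    ## provenance: varying parameters as vectors in member order
    defs <- entityDefs()
    varying <- list()
    for (k in collection@linkingEntities) {
        lm <- defs[[k]]$linked_metadata
        if (is.null(lm) || is.null(tab[[lm]])) next
        if (defs[[k]]$value_kind == "index") {
            ## one value per index, in index order (e.g. the two inversion
            ## times of a magnitude/phase MP2RAGE quartet)
            idx <- as.integer(tab[[k]])
            varying[[lm]] <- vapply(sort(unique(idx)), function(i)
                tab[[lm]][match(i, idx)], tab[[lm]][1L])
        } else {
            varying[[lm]] <- tab[[lm]]
        }
    }
    constFields <- setdiff(unique(c("MagneticFieldStrength",
                                    requiredMetadata(suffix))),
                           names(varying))
    constants <- list()
    for (f in constFields) {
        vals <- lapply(collection@members, function(m)
            m$sidecar$values[[f]])
        vals <- vals[!vapply(vals, is.null, TRUE)]
        if (length(vals) == 0L) next
        uv <- unique(unlist(vals))
        if (length(uv) == 1L) constants[[f]] <- uv
        else varying[[f]] <- unlist(vals)   # e.g. per-arm repetition times
    }
    maps <- lapply(names(fit@maps), function(ms)
        quantitativeMap(fit@maps[[ms]], ms, basedOn = rels,
                        varyingMeta = varying, constantMeta = constants))
    names(maps) <- names(fit@maps)
    list(fit = fit, maps = maps)
}

#' Fit collections of a dataset and write derivative maps
#'
#' @param root Dataset root.
#' @param suffix Collection suffix to fit (e.g. \code{"VFA"}).
#' @param out Derivative root directory (default
#'   \code{<root>/derivatives/qmribids}).
#' @param b1 Optional path to a transmit-field map NIfTI (relative percent).
#' @return Character vector of written map paths.
#' @export
fitDataset <- function(root, suffix, out = file.path(root, "derivatives",
                                                     "qmribids"),
                       b1 = NULL) {
    colls <- groupCollections(root)
    colls <- Filter(function(fc) fc@suffix == suffix, colls)
    if (length(colls) == 0L)
        stop("no '", suffix, "' collection found under ", root)
    b1map <- if (is.null(b1)) NULL else readVolume(b1)$voxels
    written <- character(0)
    for (fc in colls) {
        res <- fitCollection(fc, b1map = b1map)
        for (m in res$maps)
            written <- c(written,
                         writeMap(m, out, sub = fc@sub,
                                  folder = getSuffixSpec(suffix)$folder))
    }
    written
}
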