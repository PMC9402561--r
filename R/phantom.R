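## Digital phantom and synthetic-dataset generator.  Rasterizes geometric
## tissue regions into ground-truth parameter volumes, runs the forward
## signal models for each configured protocol, and writes a valid qMRI BIDS
## raw dataset (NIfTI volumes plus sidecar JSONs, one 3-D file per entity
## combination, shared constants at collection level to exercise
## inheritance).

.PARAM_NAMES <- c("t1", "t2", "t2star", "m0", "mtr_frac", "mtsat_delta",
                  "chi", "b1_rel")

#' Define a phantom region
#'
#' @param geometry \code{"sphere"} or \code{"box"}.
#' @param center Sphere center in voxel coordinates (length 3).
#' @param radius Sphere radius in voxels.
#' @param lo,hi Box corners in voxel coordinates (length 3, inclusive).
#' @param tissue A \code{\link{tissueParams}} object (scalar-valued).
#' @return List of class \code{phantom_region}.
#' @export
phantomRegion <- function(geometry = c("sphere", "box"), tissue,
                          center = NULL, radius = NULL,
                          lo = NULL, hi = NULL) {
    geometry <- match.arg(geometry)
    if (geometry == "sphere" && (is.null(center) || is.null(radius)))
        stop("sphere regions need center and radius")
    if (geometry == "box" && (is.null(lo) || is.null(hi)))
        stop("box regions need lo and hi corners")
    structure(list(geometry = geometry, tissue = tissue, center = center,
                   radius = radius, lo = lo, hi = hi),
              class = "phantom_region")
}

#' Define a phantom
#'
#' @param shape Grid dimensions, length 3 (default \code{c(32, 32, 32)}).
#' @param regions List of \code{\link{phantomRegion}}s; later regions
#'   overwrite earlier ones where they overlap.
#' @param background \code{\link{tissueParams}} for voxels outside all
#'   regions (default: empty space, \code{m0 = 0}).
#' @param noise List \code{list(model, sigma, seed)} with model
#'   \code{"none"} (default), \code{"gaussian"} or \code{"rician"}; sigma in
#'   signal units; seed fixed for reproducibility.
#' @return List of class \code{phantom_spec}.
#' @export
phantomSpec <- function(shape = c(32L, 32L, 32L), regions,
                        background = tissueParams(1, 0.1, 0.05, 0),
                        noise = list(model = "none", sigma = 0,
                                     seed = 42L)) {
    if (length(regions) == 0L)
        stop("phantom configuration needs at least one region")
    if (is.null(noise$model)) noise$model <- "none"
    if (!noise$model %in% c("none", "gaussian", "rician"))
        stop("noise model must be none, gaussian or rician")
    if (is.null(noise$sigma)) noise$sigma <- 0
    if (is.null(noise$seed)) noise$seed <- 42L
    for (r in regions) {
        if (r$geometry == "sphere") {
            if (any(r$center - r$radius < 0.5) ||
                any(r$center + r$radius > shape + 0.5))
                stop("region extends outside the grid")
        } else {
            if (any(r$lo < 1) || any(r$hi > shape))
                stop("region extends outside the grid")
        }
    }
    structure(list(shape = as.integer(shape), regions = regions,
                   background = background, noise = noise),
              class = "phantom_spec")
}

#' Rasterize a phantom into ground-truth parameter volumes
#'
#' @param spec A \code{\link{phantomSpec}}.
#' @return Named list of 3-D arrays, one per tissue parameter (\code{t1},
#'   \code{t2}, \code{t2star}, \code{m0}, \code{mtr_frac},
#'   \code{mtsat_delta}, \code{chi}, \code{b1_rel}).
#' @export
makePhantom <- function(spec) {
    stopifnot(inherits(spec, "phantom_spec"))
    d <- spec$shape
    vols <- lapply(.PARAM_NAMES, function(p)
        array(spec$background[[p]], dim = d))
    names(vols) <- .PARAM_NAMES
    ix <- slice.index(array(0, d), 1L)
    iy <- slice.index(array(0, d), 2L)
    iz <- slice.index(array(0, d), 3L)
    for (r in spec$regions) {
        inside <- if (r$geometry == "sphere") {
            (ix - r$center[1])^2 + (iy - r$center[2])^2 +
                (iz - r$center[3])^2 <= r$radius^2
        } else {
            ix >= r$lo[1] & ix <= r$hi[1] &
            iy >= r$lo[2] & iy <= r$hi[2] &
            iz >= r$lo[3] & iz <= r$hi[3]
        }
        for (p in .PARAM_NAMES)
            vols[[p]][inside] <- r$tissue[[p]]
    }
    vols
}

.phantomTissue <- function(vols)
    structure(vols, class = "tissue_params")

#' Default three-region phantom
#'
#' A 32^3 grid with three nested spheres carrying CSF-, gray-matter- and
#' white-matter-like parameters at 3 T (outer to inner), in empty
#' background.  Values follow commonly reported 3 T literature ranges.
#'
#' @param b1_rel Transmit-field scale applied to all three tissues
#'   (default 1).
#' @param noise Noise specification as in \code{\link{phantomSpec}}.
#' @return A \code{\link{phantomSpec}}.
#' @export
defaultPhantom <- function(b1_rel = 1,
                           noise = list(model = "none", sigma = 0,
                                        seed = 42L)) {
    ctr <- c(16.5, 16.5, 16.5)
    csf <- tissueParams(t1 = 3.5, t2 = 1.8, t2star = 0.5, m0 = 1000,
                        mtr_frac = 0.02, mtsat_delta = 0.001, chi = 0,
                        b1_rel = b1_rel)
    gm <- tissueParams(t1 = 1.35, t2 = 0.09, t2star = 0.06, m0 = 850,
                       mtr_frac = 0.30, mtsat_delta = 0.025, chi = 0.02,
                       b1_rel = b1_rel)
    wm <- tissueParams(t1 = 0.85, t2 = 0.07, t2star = 0.05, m0 = 800,
                       mtr_frac = 0.40, mtsat_delta = 0.04, chi = -0.03,
                       b1_rel = b1_rel)
    phantomSpec(shape = c(32L, 32L, 32L),
                regions = list(
                    phantomRegion("sphere", csf, center = ctr, radius = 14),
                    phantomRegion("sphere", gm, center = ctr, radius = 10),
                    phantomRegion("sphere", wm, center = ctr, radius = 6)),
                noise = noise)
}

#' Default acquisition protocols for every registered suffix
#'
#' Typical 3 T desk-scale protocols for the fitting-supported collections
#' and structurally valid placeholder protocols for the schema-only ones.
#'
#' @param suffixes Which suffixes to include (default: all registered).
#' @return Named list of protocol specifications, keyed by suffix.
#' @export
defaultProtocols <- function(suffixes = listSuffixes()) {
    all <- list(
        VFA = list(suffix = "VFA", flipsDeg = c(6, 20), tr = 0.015,
                   constants = list(MagneticFieldStrength = 3)),
        IRT1 = list(suffix = "IRT1", tis = c(0.1, 0.4, 0.9, 2.0), tr = 5.0,
                    constants = list(MagneticFieldStrength = 3)),
        MP2RAGE = list(suffix = "MP2RAGE",
                       protocol = mp2rageProtocol(
                           trPrep = 5.0, trExc = 0.0062,
                           ti = c(0.7, 2.5), flipsDeg = c(4, 5),
                           nExc = 160L),
                       constants = list(MagneticFieldStrength = 3,
                                        NumberShots = 160)),
        MESE = list(suffix = "MESE", tes = seq(0.015, 0.12, by = 0.015),
                    tr = 3.0,
                    constants = list(MagneticFieldStrength = 3)),
        MEGRE = list(suffix = "MEGRE", tes = seq(0.006, 0.06, by = 0.006),
                     tr = 0.1,
                     constants = list(MagneticFieldStrength = 3)),
        MTR = list(suffix = "MTR", flipDeg = 5, tr = 0.03,
                   constants = list(MagneticFieldStrength = 3)),
        MTS = list(suffix = "MTS",
                   protocol = mtsProtocol(flipMT = 6, trMT = 0.025,
                                          flipPD = 6, trPD = 0.025,
                                          flipT1 = 20, trT1 = 0.011),
                   constants = list(MagneticFieldStrength = 3)),
        TB1DAM = list(suffix = "TB1DAM", nominalDeg = 60,
                      constants = list()),
        TB1AFI = list(suffix = "TB1AFI",
                      protocol = afiProtocol(tr1 = 0.02, tr2 = 0.1,
                                             flipDeg = 60),
                      constants = list()),
        ## schema-only placeholders below: structurally valid data, no fitter
        MPM = list(suffix = "MPM", flipsDeg = c(6, 20), tr = 0.025,
                   tes = c(0.0023, 0.0046),
                   constants = list(MagneticFieldStrength = 3)),
        TB1EPI = list(suffix = "TB1EPI", flipsDeg = c(60, 120),
                      te = 0.02, constants = list()),
        TB1TFL = list(suffix = "TB1TFL", flipDeg = 8, constants = list()),
        TB1SRGE = list(suffix = "TB1SRGE", flipsDeg = c(4, 4),
                       tis = c(0.06, 1.8), trPrep = 2.4,
                       constants = list()),
        RB1COR = list(suffix = "RB1COR", flipDeg = 8, constants = list())
    )
    all[intersect(suffixes, names(all))]
}

.addNoise <- function(vol, noise) {
    if (noise$model == "none" || noise$sigma <= 0) return(vol)
    d <- dim(vol)
    if (noise$model == "gaussian") {
        vol + array(stats::rnorm(prod(d), sd = noise$sigma), d)
    } else {
        n1 <- array(stats::rnorm(prod(d), sd = noise$sigma), d)
        n2 <- array(stats::rnorm(prod(d), sd = noise$sigma), d)
        sqrt((vol + n1)^2 + n2^2)
    }
}

## forward-model the image volumes of one protocol; returns a list of
## members: list(entities=..., voxels=..., meta=per-file metadata), plus
## collection-level metadata
.simulateCollection <- function(suffix, proto, tissue) {
    members <- list()
    meta <- proto$constants
    add <- function(entities, voxels, fileMeta = list())
        members[[length(members) + 1L]] <<-
            list(entities = entities, voxels = voxels, meta = fileMeta)
    switch(suffix,
    VFA = {
        meta$RepetitionTimeExcitation <- proto$tr
        for (i in seq_along(proto$flipsDeg))
            add(list(flip = i),
                spgrSignal(tissue, proto$tr, proto$flipsDeg[i]),
                list(FlipAngle = proto$flipsDeg[i]))
    },
    IRT1 = {
        meta$RepetitionTimePreparation <- proto$tr
        for (i in seq_along(proto$tis))
            add(list(inv = i),
                abs(irSignal(tissue, proto$tis[i], proto$tr)),
                list(InversionTime = proto$tis[i]))
    },
    MP2RAGE = {
        p <- proto$protocol
        meta$RepetitionTimePreparation <- p$trPrep
        meta$RepetitionTimeExcitation <- p$trExc
        sg <- mp2rageBlockSignals(tissue, p)
        d <- dim(tissue$t1)
        ## smooth spatial phase ramp, common to both inversions, so that the
        ## magnitude/phase handling is genuinely exercised
        ramp <- (slice.index(array(0, d), 1L) +
                 slice.index(array(0, d), 2L)) * (pi / (4 * d[1L]))
        for (i in 1:2) {
            s <- if (i == 1L) sg$s1 else sg$s2
            ph <- Arg(s) + ramp
            fm <- list(InversionTime = p$ti[i],
                       FlipAngle = p$flipsDeg[i])
            add(list(inv = i, part = "mag"), Mod(s), fm)
            add(list(inv = i, part = "phase"), ph, fm)
        }
    },
    MESE = {
        meta$RepetitionTimeExcitation <- proto$tr
        for (i in seq_along(proto$tes))
            add(list(echo = i),
                monoexpSignal(tissue$m0, tissue$t2, proto$tes[i]),
                list(EchoTime = proto$tes[i]))
    },
    MEGRE = {
        meta$RepetitionTimeExcitation <- proto$tr
        for (i in seq_along(proto$tes))
            add(list(echo = i),
                monoexpSignal(tissue$m0, tissue$t2star, proto$tes[i]),
                list(EchoTime = proto$tes[i]))
    },
    MTR = {
        sOff <- spgrSignal(tissue, proto$tr, proto$flipDeg)
        add(list(mt = "off"), sOff, list(MTState = "off"))
        add(list(mt = "on"), sOff * (1 - tissue$mtr_frac),
            list(MTState = "on"))
    },
    MTS = {
        p <- proto$protocol
        sg <- mtsSignals(tissue, p)
        add(list(flip = 1, mt = "on"), sg$sMT,
            list(FlipAngle = p$flipMT, MTState = "on",
                 RepetitionTimeExcitation = p$trMT))
        add(list(flip = 1, mt = "off"), sg$sPD,
            list(FlipAngle = p$flipPD, MTState = "off",
                 RepetitionTimeExcitation = p$trPD))
        add(list(flip = 2, mt = "off"), sg$sT1,
            list(FlipAngle = p$flipT1, MTState = "off",
                 RepetitionTimeExcitation = p$trT1))
    },
    TB1DAM = {
        sg <- damSignals(tissue, proto$nominalDeg)
        add(list(flip = 1), sg$s1, list(FlipAngle = proto$nominalDeg))
        add(list(flip = 2), sg$s2, list(FlipAngle = 2 * proto$nominalDeg))
    },
    TB1AFI = {
        p <- proto$protocol
        a <- .deg2rad(p$flipDeg) * tissue$b1_rel
        s1 <- tissue$m0 * sin(a)
        s2 <- s1 * suppressWarnings(afiRatio(tissue, p))
        add(list(flip = 1), s1,
            list(FlipAngle = p$flipDeg, RepetitionTimeExcitation = p$tr1))
        add(list(flip = 2), s2,
            list(FlipAngle = p$flipDeg, RepetitionTimeExcitation = p$tr2))
    },
    MPM = {
        meta$RepetitionTimeExcitation <- proto$tr
        arms <- list(list(flip = 1, mt = "on",
                          deg = proto$flipsDeg[1], sc = 1 - tissue$mtr_frac),
                     list(flip = 1, mt = "off",
                          deg = proto$flipsDeg[1], sc = 1),
                     list(flip = 2, mt = "off",
                          deg = proto$flipsDeg[2], sc = 1))
        for (arm in arms)
            for (j in seq_along(proto$tes))
                add(list(echo = j, flip = arm$flip, mt = arm$mt),
                    spgrSignal(tissue, proto$tr, arm$deg,
                               te = proto$tes[j]) * arm$sc,
                    list(EchoTime = proto$tes[j], FlipAngle = arm$deg,
                         MTState = arm$mt))
    },
    TB1EPI = {
        for (i in seq_along(proto$flipsDeg)) {
            a <- .deg2rad(proto$flipsDeg[i]) * tissue$b1_rel
            add(list(echo = 1, flip = i), abs(tissue$m0 * sin(a)),
                list(EchoTime = proto$te,
                     FlipAngle = proto$flipsDeg[i]))
        }
    },
    TB1TFL = {
        add(list(), tissue$m0 * tissue$b1_rel,
            list(FlipAngle = proto$flipDeg))
    },
    TB1SRGE = {
        for (i in 1:2)
            add(list(flip = 1, inv = i),
                tissue$m0 * (1 - exp(-proto$tis[i])),
                list(FlipAngle = proto$flipsDeg[i],
                     InversionTime = proto$tis[i],
                     RepetitionTimePreparation = proto$trPrep))
    },
    RB1COR = {
        add(list(), tissue$m0, list(FlipAngle = proto$flipDeg))
    },
    stop("no simulator for suffix '", suffix, "'"))
    list(members = members, meta = meta)
}

#' Generate a synthetic qMRI BIDS dataset
#'
#' Forward-models every configured protocol on the phantom and writes a
#' valid raw dataset: \code{dataset_description.json}, a \code{sub-01} tree
#' with one 3-D NIfTI plus sidecar per entity combination (folder per the
#' schema), shared acquisition constants written once at collection level
#' (exercising sidecar inheritance).  Ground-truth parameter volumes are
#' saved in a sibling \code{<out>_truth/} directory, outside the BIDS tree.
#' Noise, if configured, is applied after forward modeling under the
#' phantom's fixed seed, so generation is reproducible.
#'
#' @param phantom A \code{\link{phantomSpec}} (default
#'   \code{\link{defaultPhantom}()}).
#' @param protocols Named list of protocol specifications (default
#'   \code{\link{defaultProtocols}()}).
#' @param outRoot Output directory for the BIDS dataset.
#' @param sub Subject label (default \code{"01"}).
#' @return \code{outRoot}, invisibly.
#' @export
generateDataset <- function(phantom = defaultPhantom(),
                            protocols = defaultProtocols(),
                            outRoot, sub = "01") {
    stopifnot(inherits(phantom, "phantom_spec"))
    vols <- makePhantom(phantom)
    tissue <- .phantomTissue(vols)
    dir.create(outRoot, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(outRoot)) stop("cannot create output root: ", outRoot)
    writeSidecarJSON(list(Name = "qmribids digital phantom",
                          BIDSVersion = "1.5.0"),
                     file.path(outRoot, "dataset_description.json"))
    set.seed(phantom$noise$seed)
    for (suffix in names(protocols)) {
        proto <- protocols[[suffix]]
        spec <- getSuffixSpec(suffix)
        folder <- file.path(outRoot, paste0("sub-", sub), spec$folder)
        dir.create(folder, recursive = TRUE, showWarnings = FALSE)
        sim <- .simulateCollection(suffix, proto, tissue)
        ## collection-level sidecar: constants shared by all members
        if (length(sim$meta)) {
            cname <- buildFilename(list(sub = sub, entities = list(),
                                        suffix = suffix, ext = ".json"))
            writeSidecarJSON(sim$meta, file.path(folder, cname))
        }
        for (m in sim$members) {
            vox <- .addNoise(m$voxels, phantom$noise)
            base <- list(sub = sub, entities = m$entities, suffix = suffix)
            img <- buildFilename(c(base, list(ext = ".nii.gz")))
            writeVolume(vox, file.path(folder, img))
            if (length(m$meta)) {
                ## per-member sidecar; for magnitude/phase pairs the sidecar
                ## is written once without the part entity and shared
                ents <- m$entities
                ents$part <- NULL
                jname <- buildFilename(list(sub = sub, entities = ents,
                                            suffix = suffix,
                                            ext = ".json"))
                jpath <- file.path(folder, jname)
                if (!file.exists(jpath)) writeSidecarJSON(m$meta, jpath)
            }
        }
    }
    truthDir <- paste0(sub("/+$", "", outRoot), "_truth")
    dir.create(truthDir, recursive = TRUE, showWarnings = FALSE)
    for (p in names(vols))
        writeVolume(vols[[p]], file.path(truthDir, paste0(p, ".nii.gz")))
    invisible(outRoot)
}

#' Read ground-truth parameter volumes of a generated dataset
#' @param outRoot The dataset root passed to \code{\link{generateDataset}}.
#' @return Named list of 3-D arrays.
#' @export
readTruth <- function(outRoot) {
    truthDir <- paste0(sub("/+$", "", outRoot), "_truth")
    out <- lapply(.PARAM_NAMES, function(p) {
        f <- file.path(truthDir, paste0(p, ".nii.gz"))
        if (!file.exists(f)) stop("missing ground-truth volume: ", f)
        readVolume(f)$voxels
    })
    names(out) <- .PARAM_NAMES
    out
}

#' Load phantom and protocol configuration from a YAML file
#'
#' The file may carry a \code{phantom} section (shape, regions with
#' geometry/tissue, background, noise) and a \code{protocols} section (a
#' list of suffixes to simulate, each with its parameters; omitted
#' parameters fall back to the defaults of
#' \code{\link{defaultProtocols}}).
#'
#' @param path Path to a YAML configuration file.
#' @return List with elements \code{phantom} (a \code{phantom_spec}) and
#'   \code{protocols}.
#' @export
loadGeneratorConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    phantom <- if (is.null(cfg$phantom)) defaultPhantom() else {
        pc <- cfg$phantom
        regions <- lapply(pc$regions, function(r) {
            tp <- do.call(tissueParams, r$tissue)
            phantomRegion(geometry = r$geometry, tissue = tp,
                          center = r$center, radius = r$radius,
                          lo = r$lo, hi = r$hi)
        })
        bg <- if (is.null(pc$background)) tissueParams(1, 0.1, 0.05, 0)
              else do.call(tissueParams, pc$background)
        noise <- if (is.null(pc$noise))
            list(model = "none", sigma = 0, seed = 42L) else pc$noise
        phantomSpec(shape = if (is.null(pc$shape)) c(32L, 32L, 32L)
                    else pc$shape,
                    regions = regions, background = bg, noise = noise)
    }
    protocols <- if (is.null(cfg$protocols)) defaultProtocols()
                 else defaultProtocols(unlist(cfg$protocols))
    list(phantom = phantom, protocols = protocols)
}
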