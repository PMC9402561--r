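## Derivatives: quantitative maps written as BIDS derivative data with
## standardized units and full provenance (BasedOn input list, varying
## acquisition parameters in vector form, inherited constants, generating
## software).  Units are never converted implicitly: a map with
## non-conforming units is an error, interchangeability being the point of
## the standard.

#' QuantitativeMap: a fitted parameter volume with units and provenance
#'
#' @slot volume 3-D array of parameter values (NaN outside the fitted
#'   mask).
#' @slot mapSuffix Registered map suffix, e.g. \code{"T1map"}.
#' @slot units Canonical units; must equal
#'   \code{\link{unitsForMap}(mapSuffix)}.
#' @slot basedOn Character vector: dataset-root-relative paths of every
#'   input image, in parameter-table order, forward slashes.
#' @slot varyingMeta Named list of vectors: acquisition parameters that vary
#'   across the inputs (e.g. \code{FlipAngle = c(6, 20)}).
#' @slot constantMeta Named list of scalars inherited from the raw sidecars
#'   (must include \code{MagneticFieldStrength} for relaxometry maps).
#' @slot software Named list: \code{Name}, \code{Version} and optionally the
#'   fit configuration.
#' @export
setClass("QuantitativeMap",
         representation(volume = "array", mapSuffix = "character",
                        units = "character", basedOn = "character",
                        varyingMeta = "list", constantMeta = "list",
                        software = "list"),
         validity = function(object) {
             if (!object@mapSuffix %in% listMapSuffixes())
                 return(paste0("unregistered map suffix: ",
                               object@mapSuffix))
             want <- unitsForMap(object@mapSuffix)
             if (!identical(object@units, want))
                 return(sprintf(
                     "units '%s' do not match the registry ('%s')",
                     object@units, want))
             relax <- c("T1map", "T2map", "T2starmap", "R1map", "R2map",
                        "R2starmap")
             if (object@mapSuffix %in% relax &&
                 is.null(object@constantMeta$MagneticFieldStrength))
                 return("relaxometry maps require MagneticFieldStrength")
             if (anyDuplicated(object@basedOn))
                 return("basedOn must list every input exactly once")
             TRUE
         })

#' @describeIn QuantitativeMap Compact display.
#' @param object A \code{QuantitativeMap}.
#' @export
setMethod("show", "QuantitativeMap", function(object) {
    cat("QuantitativeMap <", object@mapSuffix, "> [", object@units, "], ",
        paste(dim(object@volume), collapse = "x"), " voxels\n", sep = "")
    cat("  based on ", length(object@basedOn), " input file(s)\n", sep = "")
})

#' Construct a QuantitativeMap
#'
#' @param volume 3-D array.
#' @param mapSuffix Registered map suffix.
#' @param basedOn Relative paths of the input images.
#' @param varyingMeta Named list of parameter vectors across inputs.
#' @param constantMeta Named list of constant metadata.
#' @param software Generating-software block; defaults to this package and
#'   its version.
#' @return A \code{QuantitativeMap}.
#' @export
quantitativeMap <- function(volume, mapSuffix, basedOn = character(0),
                            varyingMeta = list(), constantMeta = list(),
                            software = NULL) {
    if (is.null(software))
        software <- list(Name = "qmribids",
                         Version = as.character(
                             utils::packageVersion("qmribids")))
    methods::new("QuantitativeMap", volume = as.array(volume),
                 mapSuffix = mapSuffix, units = unitsForMap(mapSuffix),
                 basedOn = basedOn, varyingMeta = varyingMeta,
                 constantMeta = constantMeta, software = software)
}

#' Accessors for QuantitativeMap
#' @param x A \code{QuantitativeMap}.
#' @return \code{mapVolume}: the 3-D array; \code{mapUnits}: units string;
#'   \code{mapBasedOn}: provenance paths.
#' @export
mapVolume <- function(x) x@volume

#' @rdname mapVolume
#' @export
mapUnits <- function(x) x@units

#' @rdname mapVolume
#' @export
mapBasedOn <- function(x) x@basedOn

.derivDatasetDescription <- function(derivRoot, software) {
    dd <- file.path(derivRoot, "dataset_description.json")
    if (!file.exists(dd))
        writeSidecarJSON(list(
            Name = paste0(software$Name, " derivatives"),
            BIDSVersion = "1.5.0",
            DatasetType = "derivative",
            GeneratedBy = list(list(Name = software$Name,
                                    Version = software$Version))), dd)
    invisible(dd)
}

#' Write a quantitative map as a BIDS derivative
#'
#' Writes \code{sub-<label>_<mapSuffix>.nii.gz} plus a sidecar carrying
#' \code{Units}, \code{BasedOn}, the varying parameter vectors, the
#' inherited constants and a \code{GeneratedBy} software block; the
#' derivatives root receives its own \code{dataset_description.json}
#' marking it as derived data.
#'
#' @param m A \code{\link{QuantitativeMap}}.
#' @param derivRoot Root of the derivative dataset (e.g.
#'   \code{<root>/derivatives/qmribids}).
#' @param sub Subject label.
#' @param folder \code{"anat"} or \code{"fmap"}.
#' @return Path of the written NIfTI, invisibly.
#' @export
writeMap <- function(m, derivRoot, sub = "01",
                     folder = c("anat", "fmap")) {
    stopifnot(is(m, "QuantitativeMap"))
    methods::validObject(m)
    folder <- match.arg(folder)
    outDir <- file.path(derivRoot, paste0("sub-", sub), folder)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    .derivDatasetDescription(derivRoot, m@software)
    base <- buildFilename(list(sub = sub, entities = list(),
                               suffix = m@mapSuffix, ext = ".nii.gz"))
    niiPath <- file.path(outDir, base)
    writeVolume(m@volume, niiPath)
    sidecar <- c(list(Units = m@units),
                 m@varyingMeta, m@constantMeta,
                 list(BasedOn = as.list(m@basedOn),
                      GeneratedBy = list(m@software)))
    writeSidecarJSON(sidecar, sub("\\.nii\\.gz$", ".json", niiPath))
    invisible(niiPath)
}

#' Read a quantitative map written by \code{\link{writeMap}}
#'
#' Validates the declared units against the registry: unit dialects (e.g.
#' milliseconds where the registry says seconds) are rejected, never
#' silently converted.  A sidecar without \code{BasedOn} yields a warning
#' (degraded provenance), not an error.
#'
#' @param path Path to the map NIfTI.
#' @return A \code{\link{QuantitativeMap}}.
#' @export
readMap <- function(path) {
    p <- parseFilename(basename(path))
    if (!p$suffix %in% listMapSuffixes())
        stop("'", p$suffix, "' is not a registered map suffix")
    jf <- sub("\\.nii(\\.gz)?$", ".json", path)
    if (!file.exists(jf))
        stop("map sidecar not found: ", jf)
    sc <- readSidecarJSON(jf)
    want <- unitsForMap(p$suffix)
    if (is.null(sc$Units))
        stop("map sidecar lacks Units (expected '", want, "')")
    if (!identical(as.character(sc$Units), want))
        stop("units mismatch for ", p$suffix, ": sidecar says '", sc$Units,
             "', registry requires '", want,
             "'; no implicit conversion is performed")
    basedOn <- unlist(sc$BasedOn)
    if (is.null(basedOn)) {
        warning("map sidecar lacks BasedOn: provenance incomplete")
        basedOn <- character(0)
    }
    software <- if (length(sc$GeneratedBy)) sc$GeneratedBy[[1L]]
                else list(Name = "unknown", Version = "unknown")
    reserved <- c("Units", "BasedOn", "GeneratedBy")
    rest <- sc[setdiff(names(sc), reserved)]
    varying <- rest[vapply(rest, function(v)
        is.numeric(v) && length(v) > 1L, TRUE)]
    constant <- rest[vapply(rest, function(v) length(v) == 1L, TRUE)]
    vol <- readVolume(path)$voxels
    quantitativeMap(vol, p$suffix, basedOn = as.character(basedOn),
                    varyingMeta = varying, constantMeta = constant,
                    software = software)
}
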