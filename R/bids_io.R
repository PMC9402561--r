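## BIDS filename parsing/building, sidecar-JSON resolution with inheritance,
## and NIfTI volume I/O.  Only the entities relevant to qMRI file collections
## are interpreted; other standard BIDS entities (acq-, run-, ...) are
## carried through opaquely.

.EXTENSIONS <- c(".nii.gz", ".nii", ".json")

#' Parse a BIDS filename into its components
#'
#' Decomposes a single path component of the form
#' \code{sub-<label>[_ses-<label>][_<entity>-<value>...]_<suffix><ext>} into
#' subject, session, entity-value pairs, suffix and extension.  qMRI linking
#' entities (\code{echo}, \code{flip}, \code{inv}, \code{mt}, \code{part})
#' are typed: index entities must be positive integers, label entities must
#' use an allowed label.  Other standard BIDS entities are preserved as
#' opaque strings; unknown entity keys are rejected.
#'
#' @param name A filename (no directory part).
#' @return A list of class \code{parsed_name} with elements \code{sub},
#'   \code{ses} (or \code{NULL}), \code{entities} (named list; integers for
#'   index entities, strings for labels), \code{extra} (named character of
#'   passthrough entities), \code{suffix} and \code{ext}.
#' @examples
#' p <- parseFilename("sub-01_inv-1_part-mag_MP2RAGE.nii.gz")
#' p$entities$inv   # 1L
#' @export
parseFilename <- function(name) {
    if (length(name) != 1L || !is.character(name))
        stop("parseFilename() expects a single filename string")
    if (grepl("[/\\\\]", name))
        stop("malformed name '", name, "': must be a single path component")
    ext <- ""
    for (e in .EXTENSIONS) {
        if (endsWith(name, e)) { ext <- e; break }
    }
    if (!nzchar(ext))
        stop("malformed name '", name, "': unsupported extension ",
             "(expected .nii, .nii.gz or .json)")
    stem <- substr(name, 1L, nchar(name) - nchar(ext))
    toks <- strsplit(stem, "_", fixed = TRUE)[[1L]]
    if (length(toks) < 2L)
        stop("malformed name '", name, "': expected 'sub-<label>_..._<suffix>'")
    suffix <- toks[length(toks)]
    if (grepl("-", suffix, fixed = TRUE))
        stop("malformed name '", name, "': missing suffix token at position ",
             nchar(stem) - nchar(suffix) + 1L)
    toks <- toks[-length(toks)]
    defs <- entityDefs()
    passthrough <- .registry()$passthrough_entities
    sub <- NULL; ses <- NULL
    entities <- list()
    extra <- structure(character(0), names = character(0))
    pos <- 1L
    for (tk in toks) {
        m <- regmatches(tk, regexec("^([a-zA-Z0-9]+)-([a-zA-Z0-9.]+)$", tk))[[1L]]
        if (length(m) != 3L)
            stop("malformed name '", name, "': bad entity token '", tk,
                 "' at position ", pos)
        key <- m[2L]; val <- m[3L]
        if (key == "sub") {
            if (!is.null(sub) || length(entities) || length(extra))
                stop("malformed name '", name, "': 'sub-' must come first")
            sub <- val
        } else if (key == "ses") {
            if (is.null(sub) || !is.null(ses) || length(entities) || length(extra))
                stop("malformed name '", name, "': 'ses-' must follow 'sub-'")
            ses <- val
        } else if (key %in% names(defs)) {
            if (key %in% names(entities))
                stop("malformed name '", name, "': duplicate entity '", key, "'")
            d <- defs[[key]]
            if (d$value_kind == "index") {
                if (!grepl("^[0-9]+$", val) || as.integer(val) < 1L)
                    stop("entity '", key, "' in '", name,
                         "': index values must be positive integers, got '",
                         val, "'")
                entities[[key]] <- as.integer(val)
            } else {
                if (!val %in% d$allowed_labels)
                    stop("entity '", key, "' in '", name, "': label '", val,
                         "' not in allowed set {",
                         paste(d$allowed_labels, collapse = ", "), "}")
                entities[[key]] <- val
            }
        } else if (key %in% passthrough) {
            if (key %in% names(extra))
                stop("malformed name '", name, "': duplicate entity '", key, "'")
            extra[[key]] <- val
        } else {
            stop("malformed name '", name, "': unknown entity key '", key,
                 "' at position ", pos)
        }
        pos <- pos + nchar(tk) + 1L
    }
    if (is.null(sub))
        stop("malformed name '", name, "': missing 'sub-' entity")
    structure(list(sub = sub, ses = ses, entities = entities,
                   extra = extra, suffix = suffix, ext = ext),
              class = "parsed_name")
}

#' Build a canonical BIDS filename
#'
#' Inverse of \code{\link{parseFilename}}: emits entities in canonical order
#' with index values zero-padded to two digits.  When the suffix is a
#' registered collection suffix, entities marked forbidden for it are
#' rejected.
#'
#' @param p A \code{parsed_name} list, or a list with the same fields
#'   (\code{sub}, optional \code{ses}, \code{entities}, optional
#'   \code{extra}, \code{suffix}, optional \code{ext}).
#' @return The filename string.
#' @examples
#' buildFilename(list(sub = "01", entities = list(flip = 1L), suffix = "VFA"))
#' # "sub-01_flip-01_VFA.nii.gz"
#' @export
buildFilename <- function(p) {
    if (is.null(p$sub)) stop("cannot build filename: missing subject")
    ext <- if (is.null(p$ext)) ".nii.gz" else p$ext
    if (!ext %in% .EXTENSIONS) stop("unsupported extension: ", ext)
    defs <- entityDefs()
    if (p$suffix %in% listSuffixes()) {
        req <- getSuffixSpec(p$suffix)$entity_req
        for (k in names(p$entities))
            if (identical(req[[k]], "forbidden"))
                stop("entity '", k, "' is forbidden for suffix '", p$suffix, "'")
    }
    toks <- paste0("sub-", p$sub)
    if (!is.null(p$ses)) toks <- c(toks, paste0("ses-", p$ses))
    for (k in intersect(.registry()$passthrough_entities, names(p$extra)))
        toks <- c(toks, paste0(k, "-", p$extra[[k]]))
    for (k in intersect(names(defs), names(p$entities))) {
        v <- p$entities[[k]]
        d <- defs[[k]]
        if (d$value_kind == "index") {
            v <- as.integer(v)
            if (is.na(v) || v < 1L)
                stop("entity '", k, "': index values must be positive integers")
            v <- sprintf("%02d", v)
        } else if (!v %in% d$allowed_labels) {
            stop("entity '", k, "': label '", v, "' not in allowed set")
        }
        toks <- c(toks, paste0(k, "-", v))
    }
    paste0(paste(c(toks, p$suffix), collapse = "_"), ext)
}

## ---- sidecar JSON ----------------------------------------------------------

#' Read a sidecar JSON file
#' @param path Path to a JSON file.
#' @return Named list of metadata values (vectors kept as vectors).
#' @export
readSidecarJSON <- function(path) {
    txt <- tryCatch(readLines(path, warn = FALSE, encoding = "UTF-8"),
                    error = function(e) stop("cannot read JSON file '", path,
                                             "': ", conditionMessage(e)))
    vals <- tryCatch(
        jsonlite::fromJSON(paste(txt, collapse = "\n"),
                           simplifyVector = TRUE, simplifyDataFrame = FALSE,
                           simplifyMatrix = FALSE),
        error = function(e) stop("invalid JSON in '", path, "': ",
                                 conditionMessage(e)))
    if (!is.list(vals))
        stop("invalid JSON in '", path, "': top level must be an object")
    names(vals) <- canonicalMetadataKey(names(vals))
    vals
}

## recursive lexicographic key sort, so serialized sidecars are byte-stable
.sortKeys <- function(x) {
    if (is.list(x) && !is.null(names(x)) && length(x)) {
        x <- x[order(names(x), method = "radix")]
        lapply(x, .sortKeys)
    } else x
}

#' Write a sidecar JSON file
#'
#' Keys are sorted lexicographically, floats carry up to 12 significant
#' digits, output is UTF-8 with 4-space indentation: byte-reproducible for
#' equal inputs.
#'
#' @param values Named list of metadata values.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeSidecarJSON <- function(values, path) {
    txt <- jsonlite::toJSON(.sortKeys(values), auto_unbox = TRUE,
                            digits = I(12), pretty = 4, null = "null")
    writeLines(txt, path, useBytes = TRUE)
    invisible(path)
}

## which JSON files apply to an image, per BIDS inheritance: the JSON must
## live on the path from dataset root to the image, its entities must be a
## subset of the image's, and its suffix must match.
.jsonApplies <- function(jp, ip) {
    if (jp$suffix != ip$suffix) return(FALSE)
    if (!identical(jp$sub, ip$sub)) return(FALSE)
    if (!is.null(jp$ses) && !identical(jp$ses, ip$ses)) return(FALSE)
    for (k in names(jp$entities))
        if (!k %in% names(ip$entities) ||
            !identical(jp$entities[[k]], ip$entities[[k]])) return(FALSE)
    for (k in names(jp$extra))
        if (!k %in% names(ip$extra) ||
            !identical(jp$extra[[k]], ip$extra[[k]])) return(FALSE)
    TRUE
}

#' Resolve sidecar metadata for an image with BIDS inheritance
#'
#' Collects every applicable JSON file on the path from the dataset root to
#' the image's directory (a JSON applies when its entities are a subset of
#' the image's and the suffix matches), and merges them root-to-leaf: a field
#' set at a deeper level, or by a more specific file at the same level,
#' overrides the shallower value.  This is what lets one collection-level
#' JSON describe e.g. both the magnitude and phase members of a pair.
#'
#' @param imagePath Path to the image file (inside \code{datasetRoot}).
#' @param datasetRoot Path to the BIDS dataset root.
#' @return A list of class \code{sidecar} with elements \code{values} (named
#'   list, one value per field after resolution) and \code{provenance}
#'   (character vector of contributing JSON paths, deepest last).  An image
#'   with no applicable JSON yields empty values and no error.
#' @export
resolveSidecar <- function(imagePath, datasetRoot) {
    root <- normalizePath(datasetRoot, winslash = "/", mustWork = TRUE)
    img <- normalizePath(imagePath, winslash = "/", mustWork = TRUE)
    rel <- .relPath(img, root)
    ip <- parseFilename(basename(img))
    parts <- strsplit(dirname(rel), "/", fixed = TRUE)[[1L]]
    if (identical(parts, ".")) parts <- character(0)
    dirs <- root
    acc <- root
    for (d in parts) {
        acc <- file.path(acc, d)
        dirs <- c(dirs, acc)
    }
    values <- list(); provenance <- character(0)
    for (d in dirs) {
        jsons <- sort(list.files(d, pattern = "\\.json$", full.names = TRUE))
        applicable <- character(0); nent <- integer(0)
        for (j in jsons) {
            jp <- tryCatch(parseFilename(basename(j)), error = function(e) NULL)
            if (is.null(jp)) next
            if (.jsonApplies(jp, ip)) {
                applicable <- c(applicable, j)
                nent <- c(nent, length(jp$entities) + length(jp$extra))
            }
        }
        ## same level: less specific first, so more specific wins on merge
        applicable <- applicable[order(nent, basename(applicable),
                                       method = "radix")]
        for (j in applicable) {
            vals <- readSidecarJSON(j)
            values[names(vals)] <- vals
            provenance <- c(provenance, j)
        }
    }
    structure(list(values = values, provenance = provenance),
              class = "sidecar")
}

.relPath <- function(path, root) {
    path <- normalizePath(path, winslash = "/", mustWork = FALSE)
    root <- normalizePath(root, winslash = "/", mustWork = FALSE)
    if (!startsWith(path, paste0(root, "/")))
        stop("'", path, "' is not inside '", root, "'")
    substring(path, nchar(root) + 2L)
}

## ---- volumes ---------------------------------------------------------------

#' Read a 3-D image volume
#' @param path Path to a NIfTI file.
#' @return List of class \code{image_volume}: \code{voxels} (3-D array),
#'   \code{affine} (4x4 matrix), \code{path}.
#' @export
readVolume <- function(path) {
    nii <- RNifti::readNifti(path)
    vox <- as.array(nii)
    attributes(vox) <- list(dim = dim(vox))   # plain base array
    if (length(dim(vox)) == 4L && dim(vox)[4L] == 1L)
        vox <- array(vox, dim(vox)[1:3])
    if (length(dim(vox)) != 3L)
        stop("'", path, "' is not a 3-D volume (one file per entity ",
             "combination is expected)")
    aff <- tryCatch(structure(RNifti::xform(nii), class = NULL),
                    error = function(e) diag(4))
    structure(list(voxels = vox, affine = unclass(aff)[1:4, 1:4], path = path),
              class = "image_volume")
}

#' Write a 3-D image volume
#' @param voxels 3-D numeric array.
#' @param path Output path (\code{.nii} or \code{.nii.gz}).
#' @param affine Optional 4x4 affine; identity spacing by default.
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(voxels, path, affine = NULL) {
    if (length(dim(voxels)) != 3L)
        stop("writeVolume() expects a 3-D array")
    img <- RNifti::asNifti(voxels)
    if (!is.null(affine))
        RNifti::qform(img) <- structure(affine, code = 2L)
    RNifti::writeNifti(img, path)
    invisible(path)
}
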