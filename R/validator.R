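## Dataset validation at filename, collection and metadata level.  Issues
## are data (a data.frame), not exceptions; each issue code has a fixed
## severity.  Metadata rules sourced from the BIDS qMRI appendix (rather
## than the convention text itself) report at warning severity unless
## strict mode is enabled.

.ISSUE_CODES <- c(
    QV_NAME_INVALID     = "error",
    QV_LABEL_INVALID    = "error",
    QV_SUFFIX_UNKNOWN   = "warning",
    QV_ENTITY_MISSING   = "error",
    QV_ENTITY_FORBIDDEN = "error",
    QV_INDEX_GAP        = "warning",
    QV_META_MISSING     = "error",
    QV_META_RECOMMENDED = "warning",
    QV_PARAM_DUPLICATE  = "error",
    QV_PARAM_INCONSISTENT = "error",
    QV_DUPLICATE_MEMBER = "error",
    QV_SIDECAR_INVALID  = "error",
    QV_UNITS_INVALID    = "error",
    QV_UNITS_MISSING    = "error",
    QV_RANGE_SUSPECT    = "warning",
    QV_PROVENANCE_MISSING = "warning")

#' Validation issue codes
#' @return Named character vector: issue code -> fixed severity.
#' @export
issueCodes <- function() .ISSUE_CODES

.issue <- function(code, path, message) {
    sev <- .ISSUE_CODES[[code]]
    if (is.null(sev)) stop("internal: unknown issue code ", code)
    data.frame(code = code, severity = sev, path = path, message = message,
               stringsAsFactors = FALSE)
}

.noIssues <- function()
    data.frame(code = character(0), severity = character(0),
               path = character(0), message = character(0),
               stringsAsFactors = FALSE)

.bindIssues <- function(...) do.call(rbind, c(list(.noIssues()), ...))

#' Check one file collection against the schema
#'
#' Verifies that (a) entities required for the suffix are present in every
#' member and forbidden ones absent; (b) index sets are contiguous from 1
#' (gaps are warnings); (c) the linked acquisition parameter of each index
#' entity is present in the metadata, constant within an index and distinct
#' across indices of \code{echo}/\code{flip}/\code{inv} (duplicates are
#' errors, since they break model fitting); and (d) the suffix's required
#' metadata fields resolve for every member.  Fields encoded from the BIDS
#' qMRI appendix (not the convention text) report as
#' \code{QV_META_RECOMMENDED} warnings unless \code{strict}.
#'
#' @param collection A \code{FileCollection} with resolved sidecars.
#' @param strict Promote appendix-sourced metadata requirements to errors.
#' @return A data.frame of issues (possibly empty) with columns \code{code},
#'   \code{severity}, \code{path}, \code{message}.
#' @export
checkCollection <- function(collection, strict = FALSE) {
    stopifnot(is(collection, "FileCollection"))
    spec <- getSuffixSpec(collection@suffix)
    defs <- entityDefs()
    issues <- list()
    members <- collection@members
    paths <- vapply(members, function(m)
        if (!is.null(m$rel)) m$rel else m$path, "")
    cid <- paste0("collection:", collection@suffix, ":sub-",
                  collection@sub)
    ## duplicate entity mappings
    sigs <- vapply(members, function(m) .entitySignature(m$parsed), "")
    if (anyDuplicated(sigs))
        for (i in which(duplicated(sigs)))
            issues <- c(issues, list(.issue("QV_DUPLICATE_MEMBER", paths[i],
                sprintf("member duplicates the entity mapping of another file (%s)",
                        sigs[i]))))
    ## (a) required / forbidden entities
    for (k in names(spec$entity_req)) {
        lev <- spec$entity_req[[k]]
        has <- vapply(members, function(m)
            k %in% names(m$parsed$entities), TRUE)
        if (lev == "required" && any(!has))
            for (i in which(!has))
                issues <- c(issues, list(.issue("QV_ENTITY_MISSING",
                    paths[i],
                    sprintf("entity '%s' is required for suffix %s", k,
                            collection@suffix))))
        if (lev == "forbidden" && any(has))
            for (i in which(has))
                issues <- c(issues, list(.issue("QV_ENTITY_FORBIDDEN",
                    paths[i],
                    sprintf("entity '%s' is not allowed for suffix %s", k,
                            collection@suffix))))
    }
    ## (b) index contiguity
    for (k in names(defs)) {
        if (defs[[k]]$value_kind != "index") next
        idx <- unlist(lapply(members, function(m) m$parsed$entities[[k]]))
        if (length(idx) == 0L) next
        idx <- sort(unique(idx))
        want <- seq_len(max(idx))
        if (!identical(idx, want))
            issues <- c(issues, list(.issue("QV_INDEX_GAP", cid,
                sprintf("%s indices {%s} are not contiguous from 1", k,
                        paste(idx, collapse = ",")))))
    }
    ## (c) linked metadata presence / consistency / distinctness
    for (k in intersect(names(defs), collection@linkingEntities)) {
        lm <- defs[[k]]$linked_metadata
        if (is.null(lm)) next
        vals <- lapply(members, function(m) {
            if (k %in% names(m$parsed$entities) && !is.null(m$sidecar))
                m$sidecar$values[[lm]] else NULL
        })
        here <- vapply(members, function(m)
            k %in% names(m$parsed$entities), TRUE)
        for (i in which(here & vapply(vals, is.null, TRUE)))
            issues <- c(issues, list(.issue("QV_META_MISSING", paths[i],
                sprintf("metadata field '%s' (linked to entity '%s') is missing",
                        lm, k))))
        if (defs[[k]]$value_kind == "index") {
            idx <- vapply(members, function(m) {
                v <- m$parsed$entities[[k]]
                if (is.null(v)) NA_integer_ else v
            }, 0L)
            num <- vapply(vals, function(v)
                if (is.null(v) || is.character(v)) NA_real_
                else as.numeric(v[1L]), 0)
            byIdx <- split(num, idx)
            for (g in names(byIdx)) {
                u <- unique(byIdx[[g]][!is.na(byIdx[[g]])])
                if (length(u) > 1L)
                    issues <- c(issues, list(.issue("QV_PARAM_INCONSISTENT",
                        cid, sprintf("'%s' varies within %s-%s", lm, k, g))))
            }
            perIdx <- vapply(byIdx, function(v) {
                v <- v[!is.na(v)]
                if (length(v)) v[1L] else NA_real_
            }, 0)
            perIdx <- perIdx[!is.na(perIdx)]
            if (k %in% c("echo", "flip", "inv") &&
                !(k %in% spec$param_distinct_exempt) &&
                anyDuplicated(perIdx))
                issues <- c(issues, list(.issue("QV_PARAM_DUPLICATE", cid,
                    sprintf("'%s' takes the same value for different %s indices",
                            lm, k))))
        }
    }
    ## (d) required metadata per suffix
    rm <- spec$required_metadata
    for (j in seq_len(nrow(rm))) {
        fld <- rm$field[j]
        miss <- vapply(members, function(m)
            is.null(m$sidecar) || is.null(m$sidecar$values[[fld]]), TRUE)
        if (!any(miss)) next
        code <- if (rm$source[j] == "core" || strict) "QV_META_MISSING"
                else "QV_META_RECOMMENDED"
        for (i in which(miss))
            issues <- c(issues, list(.issue(code, paths[i],
                sprintf("required metadata field '%s' is missing for suffix %s",
                        fld, collection@suffix))))
    }
    .bindIssues(issues)
}

## validate quantitative-map files under derivatives/
.checkDerivatives <- function(root) {
    ddir <- file.path(root, "derivatives")
    if (!dir.exists(ddir)) return(.noIssues())
    files <- list.files(ddir, pattern = "\\.nii(\\.gz)?$",
                        recursive = TRUE, full.names = TRUE)
    issues <- list()
    relax <- c("T1map", "T2map", "T2starmap", "R1map", "R2map", "R2starmap")
    for (f in files) {
        rel <- .relPath(f, root)
        p <- tryCatch(parseFilename(basename(f)), error = function(e) e)
        if (inherits(p, "error")) {
            issues <- c(issues, list(.issue("QV_NAME_INVALID", rel,
                conditionMessage(p))))
            next
        }
        if (!p$suffix %in% listMapSuffixes()) next
        jf <- sub("\\.nii(\\.gz)?$", ".json", f)
        if (!file.exists(jf)) {
            issues <- c(issues, list(.issue("QV_UNITS_MISSING", rel,
                "quantitative map lacks a sidecar declaring its units")))
            next
        }
        sc <- tryCatch(readSidecarJSON(jf), error = function(e) e)
        if (inherits(sc, "error")) {
            issues <- c(issues, list(.issue("QV_SIDECAR_INVALID", rel,
                conditionMessage(sc))))
            next
        }
        want <- unitsForMap(p$suffix)
        if (is.null(sc$Units)) {
            issues <- c(issues, list(.issue("QV_UNITS_MISSING", rel,
                sprintf("map sidecar lacks Units (expected '%s')", want))))
        } else if (!identical(as.character(sc$Units), want)) {
            issues <- c(issues, list(.issue("QV_UNITS_INVALID", rel,
                sprintf("Units '%s' does not match the registry ('%s'); no implicit conversion is performed",
                        sc$Units, want))))
        }
        if (p$suffix %in% relax && is.null(sc$MagneticFieldStrength))
            issues <- c(issues, list(.issue("QV_META_MISSING", rel,
                "relaxometry map lacks MagneticFieldStrength")))
        if (is.null(sc$BasedOn))
            issues <- c(issues, list(.issue("QV_PROVENANCE_MISSING", rel,
                "map sidecar lacks BasedOn provenance")))
        rng <- rangeForMap(p$suffix)
        if (!is.null(rng)) {
            vox <- tryCatch(readVolume(f)$voxels, error = function(e) NULL)
            if (!is.null(vox)) {
                v <- vox[is.finite(vox)]
                if (length(v) && (min(v) < rng[1L] || max(v) > rng[2L]))
                    issues <- c(issues, list(.issue("QV_RANGE_SUSPECT", rel,
                        sprintf("values outside the expected %s range [%g, %g]",
                                p$suffix, rng[1L], rng[2L]))))
            }
        }
    }
    .bindIssues(issues)
}

#' Validate a qMRI BIDS dataset
#'
#' Runs filename-, collection- and metadata-level checks over the raw data
#' and units/provenance checks over any quantitative maps under
#' \code{derivatives/}.  Never mutates the dataset; the issue list is
#' deterministic and sorted by (path, code).
#'
#' @param root Dataset root directory.
#' @param strict Promote appendix-sourced metadata requirements to errors.
#' @return A data.frame of issues with columns \code{code},
#'   \code{severity}, \code{path}, \code{message}; zero rows when the
#'   dataset is clean.
#' @export
validateDataset <- function(root, strict = FALSE) {
    if (!dir.exists(root))
        stop("dataset root does not exist: ", root)
    root <- normalizePath(root, winslash = "/", mustWork = TRUE)
    issues <- list()
    imgs <- .scanImages(root)
    for (im in imgs) {
        if (!inherits(im$parsed, "error")) next
        msg <- conditionMessage(im$parsed)
        code <- if (grepl("label '", msg, fixed = TRUE)) "QV_LABEL_INVALID"
                else "QV_NAME_INVALID"
        issues <- c(issues, list(.issue(code, im$rel, msg)))
    }
    known <- listSuffixes()
    for (im in imgs) {
        if (inherits(im$parsed, "error")) next
        if (!im$parsed$suffix %in% known)
            issues <- c(issues, list(.issue("QV_SUFFIX_UNKNOWN", im$rel,
                sprintf("suffix '%s' is not a registered qMRI file-collection suffix",
                        im$parsed$suffix))))
    }
    colls <- groupCollections(root, resolveSidecars = TRUE,
                              onDuplicate = "keep")
    for (fc in colls)
        issues <- c(issues, list(checkCollection(fc, strict = strict)))
    issues <- c(issues, list(.checkDerivatives(root)))
    out <- .bindIssues(issues)
    out <- out[order(out$path, out$code, out$message, method = "radix"), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Summarize validation issues
#' @param issues Data frame from \code{\link{validateDataset}}.
#' @return List with \code{n_errors}, \code{n_warnings}.
#' @export
issueSummary <- function(issues) {
    list(n_errors = sum(issues$severity == "error"),
         n_warnings = sum(issues$severity == "warning"))
}

#' Write a JSON validation report
#'
#' @param issues Data frame from \code{\link{validateDataset}}.
#' @param path Output path.
#' @param root Optional dataset root, recorded in the summary block.
#' @return \code{path}, invisibly.
#' @export
writeValidationReport <- function(issues, path, root = NULL) {
    colls <- 0L
    if (!is.null(root))
        colls <- length(tryCatch(
            groupCollections(root, resolveSidecars = FALSE),
            error = function(e) list()))
    rep <- list(
        issues = lapply(seq_len(nrow(issues)), function(i)
            as.list(issues[i, , drop = FALSE])),
        summary = c(issueSummary(issues), list(n_collections = colls)))
    writeLines(jsonlite::toJSON(rep, auto_unbox = TRUE, pretty = 4,
                                digits = I(12)),
               path, useBytes = TRUE)
    invisible(path)
}
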