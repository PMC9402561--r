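## Entity-linked file collections: grouping of parsed image files into the
## logical units (one per qMRI acquisition) defined by a shared suffix and
## scope, and their per-member acquisition-parameter tables.

#' FileCollection: one entity-linked qMRI file collection
#'
#' Members share subject, session, folder, suffix and all non-linking
#' entities, and differ pairwise in at least one linking entity.
#'
#' @slot suffix Collection suffix (e.g. \code{"MP2RAGE"}).
#' @slot sub Subject label.
#' @slot ses Session label or \code{NA}.
#' @slot folder \code{"anat"} or \code{"fmap"}.
#' @slot extra Named character vector of non-linking (passthrough) entities
#'   shared by all members.
#' @slot members List; each element has \code{parsed} (a
#'   \code{parsed_name}), \code{path} and \code{sidecar} (possibly
#'   \code{NULL} until resolved).
#' @slot linkingEntities Character vector of entity keys that vary across
#'   members.
#' @export
setClass("FileCollection",
         representation(suffix = "character", sub = "character",
                        ses = "character", folder = "character",
                        extra = "character", members = "list",
                        linkingEntities = "character"),
         validity = function(object) {
             ## duplicate entity mappings are rejected by groupCollections
             ## (error mode) or reported by the validator; the class itself
             ## tolerates them so issues can be represented as data
             if (length(object@members) == 0L)
                 return("a collection must have at least one member")
             TRUE
         })

.entitySignature <- function(p) {
    ents <- p$entities
    if (length(ents) == 0L) return("")
    ents <- ents[order(names(ents), method = "radix")]
    paste(names(ents), vapply(ents, as.character, ""),
          sep = "=", collapse = ",")
}

.scopeKey <- function(p, folder) {
    ex <- p$extra[order(names(p$extra), method = "radix")]
    paste(p$sub, if (is.null(p$ses)) "" else p$ses, folder, p$suffix,
          paste(names(ex), ex, sep = "=", collapse = ","), sep = "|")
}

#' @describeIn FileCollection Compact display of a collection.
#' @param object A \code{FileCollection}.
#' @export
setMethod("show", "FileCollection", function(object) {
    cat("FileCollection <", object@suffix, "> sub-", object@sub,
        if (!is.na(object@ses)) paste0(" ses-", object@ses), "\n", sep = "")
    cat("  folder: ", object@folder,
        "; members: ", length(object@members),
        "; linking entities: {",
        paste(object@linkingEntities, collapse = ", "), "}\n", sep = "")
})

#' Number of members in a collection
#' @param x A \code{FileCollection}.
#' @export
setMethod("length", "FileCollection", function(x) length(x@members))

#' Accessors for FileCollection
#' @param x A \code{FileCollection}.
#' @return \code{collectionSuffix}: the suffix; \code{collectionPaths}: member
#'   file paths; \code{linkingEntities}: entity keys varying across members.
#' @export
collectionSuffix <- function(x) x@suffix

#' @rdname collectionSuffix
#' @export
collectionPaths <- function(x) vapply(x@members, `[[`, "", "path")

#' @rdname collectionSuffix
#' @export
linkingEntities <- function(x) x@linkingEntities

## list recognized image files under a BIDS root, with their parse results
.scanImages <- function(root) {
    pat <- "\\.nii(\\.gz)?$"
    files <- list.files(root, pattern = pat, recursive = TRUE,
                        full.names = TRUE)
    ## derivatives have their own rules; skip them when scanning raw data
    rel <- vapply(files, .relPath, "", root = root)
    keep <- !startsWith(rel, "derivatives/")
    files <- files[keep]; rel <- rel[keep]
    out <- list()
    for (i in seq_along(files)) {
        p <- tryCatch(parseFilename(basename(files[i])),
                      error = function(e) e)
        out[[length(out) + 1L]] <- list(path = files[i], rel = rel[i],
                                        parsed = p)
    }
    out
}

#' Group a dataset's image files into file collections
#'
#' Every image file whose suffix is a registered collection suffix is
#' assigned to exactly one collection; the grouping key is (subject, session,
#' folder, non-linking entities, suffix).  Files with unregistered suffixes
#' are ignored here (the validator reports them).
#'
#' @param datasetRoot Path to the BIDS dataset root.
#' @param resolveSidecars Resolve each member's metadata (default
#'   \code{TRUE}).
#' @param onDuplicate \code{"error"} (default) to fail on two files with
#'   identical entity mappings, \code{"keep"} to retain both (used by the
#'   validator, which reports the duplication as an issue).
#' @return List of \code{FileCollection} objects, ordered by grouping key.
#' @export
groupCollections <- function(datasetRoot, resolveSidecars = TRUE,
                             onDuplicate = c("error", "keep")) {
    onDuplicate <- match.arg(onDuplicate)
    root <- normalizePath(datasetRoot, winslash = "/", mustWork = TRUE)
    imgs <- .scanImages(root)
    known <- listSuffixes()
    groups <- list()
    for (im in imgs) {
        if (inherits(im$parsed, "error")) next
        p <- im$parsed
        if (!p$suffix %in% known) next
        folder <- basename(dirname(im$path))
        key <- .scopeKey(p, folder)
        groups[[key]] <- c(groups[[key]], list(
            list(parsed = p, path = im$path, rel = im$rel, sidecar = NULL)))
    }
    out <- list()
    for (key in sort(names(groups))) {
        members <- groups[[key]]
        ord <- order(vapply(members, function(m) basename(m$path), ""),
                     method = "radix")
        members <- members[ord]
        sigs <- vapply(members, function(m) .entitySignature(m$parsed), "")
        if (anyDuplicated(sigs) && onDuplicate == "error") {
            dup <- members[[which(duplicated(sigs))[1L]]]
            stop("duplicate collection members with identical entity ",
                 "mappings: ", dup$rel)
        }
        ## unpadded indices are accepted on read, but mixed padding within
        ## one collection is worth flagging
        for (k in names(entityDefs())) {
            if (entityDefs()[[k]]$value_kind != "index") next
            toks <- regmatches(
                vapply(members, function(m) basename(m$path), ""),
                regexpr(paste0("(?<=_)", k, "-[0-9]+"),
                        vapply(members, function(m) basename(m$path), ""),
                        perl = TRUE))
            w <- unique(nchar(sub(paste0(k, "-"), "", toks)))
            if (length(w) > 1L)
                warning("mixed zero-padding of '", k, "' indices within ",
                        "one ", members[[1L]]$parsed$suffix, " collection")
        }
        if (resolveSidecars)
            for (i in seq_along(members))
                members[[i]]$sidecar <- resolveSidecar(members[[i]]$path, root)
        p1 <- members[[1L]]$parsed
        allKeys <- unique(unlist(lapply(members,
                                        function(m) names(m$parsed$entities))))
        varying <- character(0)
        for (k in allKeys) {
            vals <- lapply(members, function(m) m$parsed$entities[[k]])
            if (any(vapply(vals, is.null, TRUE)) ||
                length(unique(vapply(vals, as.character, ""))) > 1L)
                varying <- c(varying, k)
        }
        if (length(members) > 1L && length(varying) == 0L) varying <- allKeys
        fc <- methods::new("FileCollection",
                  suffix = p1$suffix, sub = p1$sub,
                  ses = if (is.null(p1$ses)) NA_character_ else p1$ses,
                  folder = basename(dirname(members[[1L]]$path)),
                  extra = if (length(p1$extra)) p1$extra else
                      structure(character(0), names = character(0)),
                  members = members,
                  linkingEntities = sort(varying))
        out[[length(out) + 1L]] <- fc
    }
    out
}

#' Per-member acquisition-parameter table of a collection
#'
#' One row per member: the linking-entity values from the filename and the
#' associated acquisition-parameter values read from the resolved sidecar
#' metadata (never from the filename).  Enforces that, within a fixed index
#' of an index entity, the linked parameter is constant, and that it differs
#' across indices of \code{echo}, \code{flip} and \code{inv} (unless the
#' suffix is exempt, as for dual-TR flip-angle imaging where the two volumes
#' share one nominal flip angle).
#'
#' @param collection A \code{FileCollection} whose members carry resolved
#'   sidecars.
#' @return A \code{data.frame}, one row per member, columns: \code{file},
#'   one column per entity present, one column per linked parameter.
#' @export
parameterTable <- function(collection) {
    stopifnot(is(collection, "FileCollection"))
    members <- collection@members
    defs <- entityDefs()
    spec <- getSuffixSpec(collection@suffix)
    ekeys <- unique(unlist(lapply(members,
                                  function(m) names(m$parsed$entities))))
    ekeys <- intersect(names(defs), ekeys)
    df <- data.frame(file = vapply(members, function(m) basename(m$path), ""),
                     stringsAsFactors = FALSE)
    for (k in ekeys) {
        vals <- lapply(members, function(m) m$parsed$entities[[k]])
        df[[k]] <- vapply(vals, function(v)
            if (is.null(v)) NA_character_ else as.character(v), "")
        lm <- defs[[k]]$linked_metadata
        if (is.null(lm)) next
        mv <- vapply(members, function(m) {
            if (is.null(m$sidecar))
                stop("parameterTable() needs resolved sidecars; rerun ",
                     "groupCollections(resolveSidecars = TRUE)")
            v <- m$sidecar$values[[lm]]
            if (is.null(v)) NA_real_ else suppressWarnings(
                if (is.character(v)) NA_real_ else as.numeric(v[1L]))
        }, 0)
        if (defs[[k]]$value_kind == "label") {
            mv <- vapply(members, function(m) {
                v <- m$sidecar$values[[lm]]
                if (is.null(v)) NA_character_ else as.character(v)
            }, "")
        }
        miss <- is.na(mv) & !is.na(df[[k]])
        if (any(miss))
            stop("incomplete parameter table for ", collection@suffix,
                 ": member '", df$file[which(miss)[1L]],
                 "' lacks metadata field '", lm, "'")
        df[[lm]] <- mv
        ## consistency within index / distinctness across indices
        if (defs[[k]]$value_kind == "index") {
            idx <- df[[k]]
            byIdx <- split(mv, idx)
            for (g in names(byIdx))
                if (length(unique(byIdx[[g]])) > 1L)
                    stop("inconsistent parameter table for ",
                         collection@suffix, ": '", lm, "' varies within ",
                         k, "-", g)
            perIdx <- vapply(byIdx, `[[`, 0, 1L)
            if (k %in% c("echo", "flip", "inv") &&
                !(k %in% spec$param_distinct_exempt) &&
                anyDuplicated(perIdx))
                stop("inconsistent parameter table for ", collection@suffix,
                     ": '", lm, "' duplicated across ", k, " indices")
        }
    }
    df
}

#' Export a parameter table as TSV
#' @param collection A \code{FileCollection} with resolved sidecars.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeParameterTable <- function(collection, path) {
    df <- parameterTable(collection)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
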