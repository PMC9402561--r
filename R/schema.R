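## Schema registry: the machine-readable description of the qMRI
## file-collection convention (suffixes, linking entities, requirement
## levels, metadata fields, map units).  The registry is shipped as a
## declarative YAML file under inst/schema/ and loaded once per session.

.registry_env <- new.env(parent = emptyenv())

#' Load the qMRI schema registry
#'
#' Reads the declarative registry file shipped with the package (or a
#' user-supplied one), validates it against the internal meta-schema and
#' caches it for the session.  All other schema accessors draw from this
#' cache.
#'
#' @param path Path to a registry YAML file. Defaults to the file shipped
#'   with the package.
#' @param force Reload even if a registry is already cached.
#' @return The registry, invisibly: a list with elements \code{entities},
#'   \code{passthrough_entities}, \code{metadata_aliases}, \code{suffixes}
#'   and \code{maps}.
#' @export
loadRegistry <- function(path = NULL, force = FALSE) {
    if (!force && is.null(path) && !is.null(.registry_env$registry))
        return(invisible(.registry_env$registry))
    if (is.null(path))
        path <- system.file("schema", "qmri-registry.yaml", package = "qmribids")
    if (!nzchar(path) || !file.exists(path))
        stop("schema registry file not found: ", path)
    reg <- yaml::read_yaml(path)
    .checkRegistry(reg)
    ## normalize defaults
    for (s in names(reg$suffixes)) {
        rec <- reg$suffixes[[s]]
        if (is.null(rec$entity_req)) rec$entity_req <- list()
        if (is.null(rec$required_metadata)) rec$required_metadata <- list()
        if (is.null(rec$singleton_ok)) rec$singleton_ok <- FALSE
        if (is.null(rec$param_distinct_exempt)) rec$param_distinct_exempt <- character(0)
        reg$suffixes[[s]] <- rec
    }
    .registry_env$registry <- reg
    invisible(reg)
}

## Internal meta-schema: structural checks on a registry before it is used.
.checkRegistry <- function(reg) {
    need <- c("entities", "suffixes", "maps")
    miss <- setdiff(need, names(reg))
    if (length(miss))
        stop("registry is missing top-level sections: ", paste(miss, collapse = ", "))
    ekeys <- names(reg$entities)
    if (anyDuplicated(ekeys))
        stop("registry defines duplicate entity keys")
    for (k in ekeys) {
        e <- reg$entities[[k]]
        if (!e$value_kind %in% c("index", "label"))
            stop("entity '", k, "': value_kind must be 'index' or 'label'")
        if (e$value_kind == "label" && length(e$allowed_labels) == 0)
            stop("entity '", k, "': label entities need allowed_labels")
    }
    for (s in names(reg$suffixes)) {
        rec <- reg$suffixes[[s]]
        if (!rec$folder %in% c("anat", "fmap"))
            stop("suffix '", s, "': folder must be 'anat' or 'fmap'")
        bad <- setdiff(names(rec$entity_req), ekeys)
        if (length(bad))
            stop("suffix '", s, "': unknown entities in entity_req: ",
                 paste(bad, collapse = ", "))
        for (k in names(rec$entity_req)) {
            lv <- rec$entity_req[[k]]$level
            if (!lv %in% c("required", "optional"))
                stop("suffix '", s, "': entity level must be required/optional")
        }
        for (m in rec$derived_maps)
            if (is.null(reg$maps[[m]]))
                stop("suffix '", s, "': derived map '", m, "' has no units entry")
        ## linked metadata of every required index entity must be required
        for (k in names(rec$entity_req)) {
            if (rec$entity_req[[k]]$level != "required") next
            lm <- reg$entities[[k]]$linked_metadata
            if (is.null(lm)) next
            flds <- vapply(rec$required_metadata, `[[`, "", "field")
            if (!lm %in% flds)
                stop("suffix '", s, "': required entity '", k,
                     "' links to metadata '", lm,
                     "' which is absent from required_metadata")
        }
    }
    for (m in names(reg$maps)) {
        if (is.null(reg$maps[[m]]$units))
            stop("map '", m, "': missing units")
    }
    invisible(TRUE)
}

.registry <- function() loadRegistry()

#' List registered collection suffixes
#' @return Character vector of suffixes (e.g. \code{"MP2RAGE"}, \code{"VFA"}).
#' @export
listSuffixes <- function() names(.registry()$suffixes)

#' List registered quantitative map suffixes
#' @return Character vector of map suffixes (e.g. \code{"T1map"}).
#' @export
listMapSuffixes <- function() names(.registry()$maps)

#' Linking-entity definitions
#'
#' @return Named list of entity definitions. Each has \code{value_kind}
#'   (\code{"index"} or \code{"label"}), \code{allowed_labels} (for label
#'   entities) and \code{linked_metadata} (the acquisition parameter the
#'   entity indexes, or \code{NULL} for \code{part}).
#' @export
entityDefs <- function() .registry()$entities

## canonical ordering of entities in a filename
.entityOrder <- function() {
    reg <- .registry()
    c(reg$passthrough_entities, names(reg$entities))
}

#' Retrieve the schema record for a collection suffix
#'
#' @param suffix Collection suffix, e.g. \code{"MP2RAGE"}.
#' @return A list with elements \code{suffix}, \code{folder} (\code{"anat"}
#'   or \code{"fmap"}), \code{entity_req} (named list mapping entity key to
#'   \code{"required"}/\code{"optional"}/\code{"forbidden"} over all
#'   registered entities), \code{entity_source}, \code{required_metadata}
#'   (data.frame with columns \code{field}, \code{source}),
#'   \code{derived_maps}, \code{singleton_ok} and
#'   \code{param_distinct_exempt}.
#' @examples
#' spec <- getSuffixSpec("MP2RAGE")
#' spec$entity_req[["inv"]]   # "required"
#' @export
getSuffixSpec <- function(suffix) {
    reg <- .registry()
    rec <- reg$suffixes[[suffix]]
    if (is.null(rec))
        stop("unknown file-collection suffix: '", suffix,
             "' (proprietary sequence names and weighting labels are not ",
             "collection suffixes; see listSuffixes())")
    req <- vapply(names(reg$entities), function(k) {
        lv <- rec$entity_req[[k]]$level
        if (is.null(lv)) "forbidden" else lv
    }, "")
    src <- vapply(names(reg$entities), function(k) {
        s <- rec$entity_req[[k]]$source
        if (is.null(s)) NA_character_ else s
    }, "")
    rm <- if (length(rec$required_metadata)) {
        data.frame(
            field  = vapply(rec$required_metadata, `[[`, "", "field"),
            source = vapply(rec$required_metadata, `[[`, "", "source"),
            stringsAsFactors = FALSE)
    } else data.frame(field = character(0), source = character(0),
                      stringsAsFactors = FALSE)
    list(suffix = suffix,
         folder = rec$folder,
         entity_req = as.list(req),
         entity_source = as.list(src),
         required_metadata = rm,
         derived_maps = as.character(rec$derived_maps),
         singleton_ok = isTRUE(rec$singleton_ok),
         param_distinct_exempt = as.character(rec$param_distinct_exempt))
}

#' Canonical units of a quantitative map
#'
#' Relaxation times are stored in seconds, rates in reciprocal seconds,
#' ratio maps in percent, susceptibility in ppm and transmit-field maps in
#' relative percent (100 = nominal).
#'
#' @param mapSuffix Map suffix, e.g. \code{"T1map"}.
#' @return Units string.
#' @examples
#' unitsForMap("T1map")   # "s"
#' unitsForMap("Chimap")  # "ppm"
#' @export
unitsForMap <- function(mapSuffix) {
    m <- .registry()$maps[[mapSuffix]]
    if (is.null(m))
        stop("unknown map suffix: '", mapSuffix, "'")
    m$units
}

#' Valid value range of a quantitative map
#' @param mapSuffix Map suffix.
#' @return Numeric length-2 vector \code{c(lo, hi)}, or \code{NULL} when the
#'   map has arbitrary units and no range is enforced.
#' @export
rangeForMap <- function(mapSuffix) {
    m <- .registry()$maps[[mapSuffix]]
    if (is.null(m))
        stop("unknown map suffix: '", mapSuffix, "'")
    if (is.null(m$valid_range)) NULL else as.numeric(m$valid_range)
}

#' Required metadata fields for a collection suffix
#'
#' The list contains the acquisition parameter linked to each required index
#' entity plus the collection-specific constants; \code{MagneticFieldStrength}
#' appears for every collection whose derivable maps include relaxometry
#' parameters, since those cannot be interpreted without the field strength.
#'
#' @param suffix Collection suffix.
#' @param source \code{"all"} (default), \code{"core"} or \code{"appendix"}:
#'   restrict to fields stated by the convention text itself (\code{core}) or
#'   encoded from the BIDS qMRI appendix (\code{appendix}).
#' @return Character vector of metadata field names.
#' @export
requiredMetadata <- function(suffix, source = c("all", "core", "appendix")) {
    source <- match.arg(source)
    rm <- getSuffixSpec(suffix)$required_metadata
    if (source != "all") rm <- rm[rm$source == source, , drop = FALSE]
    rm$field
}

#' Normalize a metadata key to its canonical spelling
#'
#' Some fields circulate under two spellings (e.g. the RF spoiling phase
#' increment); this maps accepted aliases onto the canonical registry key.
#'
#' @param field Metadata field name(s).
#' @return Canonicalized field name(s).
#' @export
canonicalMetadataKey <- function(field) {
    al <- .registry()$metadata_aliases
    out <- field
    for (i in seq_along(out))
        if (!is.null(al[[out[i]]])) out[i] <- al[[out[i]]]
    out
}
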