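#' Normalize an enzyme or product name for matching
#'
#' Names in the ENZYME flat file end in a period while GenBank `/product`
#' qualifiers do not; case and spacing also differ between the two sources.
#' Normalization makes the two comparable: surrounding quotes are removed,
#' whitespace runs collapse to single spaces, trailing periods are stripped
#' and the result is lower-cased. The function is idempotent, so index keys
#' are stable under re-normalization.
#'
#' @param x character vector of names.
#' @return character vector of normalized keys.
#' @examples
#' normalizeEnzymeName("Cystathionine  gamma-lyase.")
#' @export
normalizeEnzymeName <- function(x) {
    x <- trimws(x)
    x <- sub("^[\"']+", "", x)
    x <- sub("[\"']+$", "", x)
    x <- gsub("[[:space:]]+", " ", x)
    x <- sub("\\.+$", "", x)
    x <- trimws(x)
    tolower(x)
}

.NORMALIZATION_ID <- "lowercase/strip-trailing-period/collapse-ws/strip-quotes"

#' Order EC numbers in ascending numeric order
#'
#' Orders dotted EC identifiers by their four fields numerically; a `-` in
#' the fourth field (a preliminary, partial identifier) sorts after any
#' digit. Ties (identical strings) keep input order.
#'
#' @param ecs character vector of EC identifiers.
#' @return integer permutation, as from [order()].
#' @keywords internal
orderEc <- function(ecs) {
    if (!length(ecs)) return(integer())
    parts <- strsplit(ecs, ".", fixed = TRUE)
    key <- function(i) vapply(parts, function(p) {
        v <- if (length(p) >= i) p[i] else "-"
        if (v == "-") Inf else suppressWarnings(as.numeric(v))
    }, numeric(1))
    order(key(1), key(2), key(3), key(4), ecs)
}

sortEc <- function(ecs) ecs[orderEc(ecs)]

.emptyEnzymeRecords <- function() {
    data.frame(ec_number = character(), recommended_name = character(),
               alt_names = I(list()), catalytic_activity = character(),
               status = character(), transfer_targets = I(list()),
               partial = logical(), stringsAsFactors = FALSE)
}

#' Parse an ENZYME flat file into enzyme records
#'
#' Reads the line-coded ExPASy ENZYME dialect: records are blocks of
#' `ID`/`DE`/`AN`/`CA` (and ignored `CC` etc.) lines terminated by `//`.
#' Multi-line `DE` and `CA` fields are concatenated with single spaces; each
#' `AN` line contributes one alternative name. Trailing periods are stripped
#' from names and reaction text. A `DE` of the form "Transferred entry: ..."
#' yields `status = "transferred"` with the target EC numbers parsed from
#' the text; "Deleted entry." yields `status = "deleted"`; every other
#' record is `active`.
#'
#' A block whose `ID` line does not carry a syntactically valid EC number is
#' reported as a warning (with its line number) and skipped; parsing
#' continues. A final block not closed by `//` is dropped with a warning.
#'
#' @param input path to a flat file, a connection, or a character vector of
#'   lines (`textConnection`-free convenience for tests and fixtures).
#' @return data.frame of enzyme records, one row per `ID ... //` block,
#'   with the columns documented in [EnzymeDb-class].
#' @seealso [readEnzymeDb()] which also builds the name index.
#' @examples
#' rec <- parseEnzymeDat(c(
#'   "ID   4.4.1.1",
#'   "DE   Cystathionine gamma-lyase.",
#'   "CA   L-cystathionine + H2O = L-cysteine + NH3 + 2-oxobutanoate.",
#'   "//"))
#' rec$recommended_name
#' @export
parseEnzymeDat <- function(input) {
    lines <- if (is.character(input) && length(input) == 1L &&
                 !grepl("\n", input) && file.exists(input))
        readLines(input, warn = FALSE)
    else if (inherits(input, "connection"))
        readLines(input, warn = FALSE)
    else
        as.character(input)

    recs <- list()
    cur <- NULL
    curStart <- NA_integer_
    flush <- function(cur, lineno) {
        if (is.null(cur)) return(NULL)
        if (is.null(cur$id)) {
            warning("record ending at line ", lineno,
                    " has no valid ID line; skipped", call. = FALSE)
            return(NULL)
        }
        de <- paste(cur$de, collapse = " ")
        name <- sub("\\.+$", "", trimws(de))
        status <- "active"
        targets <- character()
        if (grepl("^Transferred entry", de, ignore.case = TRUE)) {
            status <- "transferred"
            targets <- regmatches(de,
                gregexpr("[0-9]+\\.[0-9]+\\.[0-9]+\\.([0-9]+|-)", de))[[1]]
            name <- ""
        } else if (grepl("^Deleted entry", de, ignore.case = TRUE)) {
            status <- "deleted"
            name <- ""
        }
        an <- sub("\\.+$", "", trimws(cur$an))
        ca <- sub("\\.+$", "", trimws(paste(cur$ca, collapse = " ")))
        list(ec_number = cur$id, recommended_name = name,
             alt_names = an, catalytic_activity = ca,
             status = status, transfer_targets = targets,
             partial = grepl("-$", cur$id))
    }

    for (i in seq_along(lines)) {
        line <- lines[i]
        code <- substr(line, 1L, 2L)
        val <- trimws(substr(line, 6L, nchar(line)))
        if (code == "//") {
            r <- flush(cur, i)
            if (!is.null(r)) recs[[length(recs) + 1L]] <- r
            cur <- NULL
        } else if (code == "ID") {
            if (!is.null(cur)) {
                # missing terminator: close out the previous block anyway
                r <- flush(cur, i)
                if (!is.null(r)) recs[[length(recs) + 1L]] <- r
            }
            curStart <- i
            if (grepl(.EC_PATTERN, val)) {
                cur <- list(id = val, de = character(), an = character(),
                            ca = character())
            } else {
                warning("malformed ID line at line ", i, ": '", val,
                        "'; record skipped", call. = FALSE)
                cur <- NULL
            }
        } else if (!is.null(cur)) {
            if (code == "DE") cur$de <- c(cur$de, val)
            else if (code == "AN") cur$an <- c(cur$an, val)
            else if (code == "CA") cur$ca <- c(cur$ca, val)
            # other line codes (CC, PR, DR, ...) are ignored
        }
    }
    if (!is.null(cur))
        warning("truncated final record starting at line ", curStart,
                " (no '//'); dropped", call. = FALSE)

    if (!length(recs)) return(.emptyEnzymeRecords())
    data.frame(
        ec_number = vapply(recs, `[[`, "", "ec_number"),
        recommended_name = vapply(recs, `[[`, "", "recommended_name"),
        alt_names = I(lapply(recs, `[[`, "alt_names")),
        catalytic_activity = vapply(recs, `[[`, "", "catalytic_activity"),
        status = vapply(recs, `[[`, "", "status"),
        transfer_targets = I(lapply(recs, `[[`, "transfer_targets")),
        partial = vapply(recs, `[[`, NA, "partial"),
        stringsAsFactors = FALSE)
}

#' Serialize enzyme records back to the ENZYME flat-file dialect
#'
#' Inverse of [parseEnzymeDat()] for the fields this package models;
#' re-parsing the output yields field-identical records.
#'
#' @param records data.frame of enzyme records (see [EnzymeDb-class]).
#' @param path optional output file; when `NULL` the lines are returned.
#' @return character vector of lines, invisibly when written to `path`.
#' @export
writeEnzymeDat <- function(records, path = NULL) {
    blocks <- lapply(seq_len(nrow(records)), function(i) {
        r <- records[i, ]
        out <- paste0("ID   ", r$ec_number)
        if (r$status == "transferred") {
            tg <- r$transfer_targets[[1]]
            txt <- if (length(tg) > 1L)
                paste0(paste(tg[-length(tg)], collapse = ", "), " and ",
                       tg[length(tg)])
            else tg
            out <- c(out, paste0("DE   Transferred entry: ", txt, "."))
        } else if (r$status == "deleted") {
            out <- c(out, "DE   Deleted entry.")
        } else {
            out <- c(out, paste0("DE   ", r$recommended_name, "."))
        }
        for (an in r$alt_names[[1]])
            out <- c(out, paste0("AN   ", an, "."))
        if (nzchar(r$catalytic_activity))
            out <- c(out, paste0("CA   ", r$catalytic_activity, "."))
        c(out, "//")
    })
    lines <- unlist(blocks, use.names = FALSE)
    if (is.null(lines)) lines <- character()
    if (!is.null(path)) {
        writeLines(lines, path)
        return(invisible(lines))
    }
    lines
}

#' Build the name index over active enzyme records
#'
#' Every *active* record contributes its recommended name and each of its
#' alternative names as normalized keys; transferred and deleted entries are
#' excluded entirely. A key claimed by k distinct EC numbers maps to all k,
#' in ascending EC order — collisions are data (they drive the multi-match
#' annotation outcome), not errors.
#'
#' @param records data.frame of enzyme records from [parseEnzymeDat()].
#' @return named list mapping normalized name to a character vector of EC
#'   numbers in ascending EC order; keys sorted for determinism.
#' @export
buildNameIndex <- function(records) {
    act <- records[records$status == "active", , drop = FALSE]
    if (!nrow(act)) return(structure(list(), names = character()))
    keys <- mapply(function(nm, alt) unique(normalizeEnzymeName(c(nm, alt))),
                   act$recommended_name, act$alt_names, SIMPLIFY = FALSE)
    pairs <- data.frame(
        key = unlist(keys, use.names = FALSE),
        ec = rep(act$ec_number, lengths(keys)),
        stringsAsFactors = FALSE)
    pairs <- pairs[nzchar(pairs$key), , drop = FALSE]
    idx <- lapply(split(pairs$ec, pairs$key), function(e) sortEc(unique(e)))
    idx[order(names(idx))]
}

#' Construct an EnzymeDb from parsed records
#'
#' @param records data.frame of enzyme records ([parseEnzymeDat()]).
#' @return an [EnzymeDb-class] object with its name index built.
#' @export
EnzymeDb <- function(records = .emptyEnzymeRecords()) {
    new("EnzymeDb", records = records, index = buildNameIndex(records),
        normalization = .NORMALIZATION_ID)
}

#' Read an ENZYME flat file into an EnzymeDb
#'
#' @param path file path (or connection, or character lines) in the ENZYME
#'   flat-file dialect.
#' @return an [EnzymeDb-class] object.
#' @export
readEnzymeDb <- function(path) EnzymeDb(parseEnzymeDat(path))

#' @describeIn EnzymeDb the record table.
#' @param x,object an `EnzymeDb`.
#' @export
enzymeRecords <- function(x) {
    stopifnot(is(x, "EnzymeDb"))
    x@records
}

#' @describeIn EnzymeDb the normalized-name index (named list of EC
#'   vectors).
#' @export
nameIndex <- function(x) {
    stopifnot(is(x, "EnzymeDb"))
    x@index
}

#' Look up one EC number in the database
#'
#' Fills the report columns: the predominant (recommended) name associated
#' with an EC number and its catalyzed reaction. An EC absent from the
#' database yields a distinguishable not-found result rather than an error,
#' so a comparison run continues and the report carries a sentinel.
#'
#' @param db an [EnzymeDb-class].
#' @param ec a single EC identifier (syntactically valid).
#' @return a list with elements `ec_number`, `found` (logical),
#'   `recommended_name`, `alt_names`, `catalytic_activity`, `status` and
#'   `transfer_targets`. When `found` is `FALSE` the text fields are empty
#'   and `status` is `"not_found"`.
#' @export
lookupEc <- function(db, ec) {
    stopifnot(is(db, "EnzymeDb"), length(ec) == 1L)
    if (!grepl(.EC_PATTERN, ec))
        stop("not a syntactically valid EC number: ", ec)
    i <- match(ec, db@records$ec_number)
    if (is.na(i))
        return(list(ec_number = ec, found = FALSE, recommended_name = "",
                    alt_names = character(), catalytic_activity = "",
                    status = "not_found", transfer_targets = character()))
    r <- db@records[i, ]
    list(ec_number = ec, found = TRUE,
         recommended_name = r$recommended_name,
         alt_names = r$alt_names[[1]],
         catalytic_activity = r$catalytic_activity,
         status = r$status, transfer_targets = r$transfer_targets[[1]])
}

#' @rdname EnzymeDb-class
#' @export
setMethod("show", "EnzymeDb", function(object) {
    rec <- object@records
    cat("EnzymeDb with", nrow(rec), "records (",
        sum(rec$status == "active"), "active,",
        sum(rec$status == "transferred"), "transferred,",
        sum(rec$status == "deleted"), "deleted )\n")
    cat("  name index:", length(object@index), "normalized keys (",
        sum(lengths(object@index) > 1L), "shared by >1 EC )\n")
    cat("  normalization:", object@normalization, "\n")
})
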