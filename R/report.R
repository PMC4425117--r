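## Three-section tabular report. TSV is the canonical output format (the
## presentation layer of the original methodology is out of scope here):
## diff-able, parseable, and byte-identical across runs on the same inputs.

.REPORT_COLS <- c("gi_accession", "organism", "ec_number", "ec_name",
                  "biochemistry", "reliability", "microbiome")

#' Render a comparison result as a three-section TSV report
#'
#' Sections are delimited by labelled header lines (`## section: ...`); each
#' section repeats the column header. Columns are exactly `gi_accession`,
#' `organism`, `ec_number`, `ec_name`, `biochemistry`, `reliability`,
#' `microbiome`. Leading `#` lines carry the group labels and any run
#' configuration for provenance. Output is UTF-8 and deterministic.
#'
#' @param result a [ComparisonResult-class].
#' @param config optional named list (e.g. from [newRunConfig()]) echoed
#'   verbatim into the report header.
#' @return character vector of report lines.
#' @seealso [parseReport()] for the inverse.
#' @export
renderReport <- function(result, config = NULL) {
    stopifnot(is(result, "ComparisonResult"))
    labs <- comparisonLabels(result)
    out <- c("# enzymome comparison report",
             paste0("# group_a: ", labs[1]),
             paste0("# group_b: ", labs[2]))
    if (!is.null(config))
        out <- c(out, vapply(names(config), function(k)
            paste0("# config ", k, ": ",
                   paste(format(config[[k]]), collapse = " ")), ""))
    rows <- comparisonRows(result)
    secTitle <- c(identical = paste0("identical (", labs[1], " ∩ ",
                                     labs[2], ")"),
                  unique_a = paste0("unique to ", labs[1]),
                  unique_b = paste0("unique to ", labs[2]))
    for (sec in c("identical", "unique_a", "unique_b")) {
        sub <- rows[rows$section == sec, .REPORT_COLS, drop = FALSE]
        out <- c(out,
                 paste0("## section: ", sec, " — ", secTitle[[sec]]),
                 paste(.REPORT_COLS, collapse = "\t"),
                 if (nrow(sub)) do.call(paste,
                                        c(unname(as.list(sub)), sep = "\t")))
    }
    out
}

#' Parse a rendered report back into its rows
#'
#' Inverse of [renderReport()]: reconstructs the classified row table
#' (including the `section` column) from the TSV text.
#'
#' @param lines character vector of report lines, or a file path.
#' @return data.frame with the same columns as [comparisonRows()].
#' @export
parseReport <- function(lines) {
    if (length(lines) == 1L && file.exists(lines))
        lines <- readLines(lines, warn = FALSE)
    sec <- NA_character_
    rows <- list()
    for (line in lines) {
        if (grepl("^## section: ", line)) {
            sec <- sub("^## section: (\\S+).*$", "\\1", line)
        } else if (grepl("^#", line) || !nzchar(line) ||
                   startsWith(line, "gi_accession\t")) {
            next
        } else if (!is.na(sec)) {
            f <- strsplit(line, "\t", fixed = TRUE)[[1]]
            length(f) <- length(.REPORT_COLS)
            rows[[length(rows) + 1L]] <- c(section = sec,
                                           stats::setNames(f, .REPORT_COLS))
        }
    }
    if (!length(rows)) {
        out <- data.frame(section = character(),
                          gi_accession = character(), organism = character(),
                          ec_number = character(), ec_name = character(),
                          biochemistry = character(),
                          reliability = integer(),
                          microbiome = character(), stringsAsFactors = FALSE)
        return(out)
    }
    out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    out$reliability <- as.integer(out$reliability)
    out
}

#' Validated run configuration
#'
#' Collects and validates everything one comparison run needs before any
#' I/O happens; the configuration is echoed into the report header for
#' provenance.
#'
#' @param groupA,groupB character vectors of GenBank file paths, or a single
#'   directory containing `.gb`/`.gbk`/`.gbff` files.
#' @param labelA,labelB group labels (defaults "Microbiome 1"/"Microbiome
#'   2"); must differ.
#' @param enzymeDat path to an ENZYME flat file, or `NULL` (no de novo
#'   annotation; report name/biochemistry columns unresolved).
#' @param annotateMode `"unique+multi"`, `"unique-only"` or `"off"`.
#' @param substringFallback enable the substring fallback of
#'   [matchProduct()].
#' @param outPrefix path prefix for the report, summary and coverage TSVs.
#' @param skipBadFiles skip unreadable genome files with a warning instead
#'   of aborting.
#' @param seed optional integer recorded for provenance (comparison itself
#'   is deterministic).
#' @return validated config (named list of class `enzymomeRunConfig`).
#' @export
newRunConfig <- function(groupA, groupB,
                         labelA = "Microbiome 1", labelB = "Microbiome 2",
                         enzymeDat = NULL,
                         annotateMode = c("unique+multi", "unique-only",
                                          "off"),
                         substringFallback = FALSE,
                         outPrefix = "enzymome",
                         skipBadFiles = FALSE, seed = NULL) {
    annotateMode <- match.arg(annotateMode)
    expand <- function(paths, what) {
        if (length(paths) == 1L && dir.exists(paths))
            paths <- sort(list.files(paths, "\\.(gb|gbk|gbff)$",
                                     full.names = TRUE))
        if (!length(paths))
            stop("group ", what, " contains no GenBank files")
        missing <- paths[!file.exists(paths)]
        if (length(missing))
            stop("group ", what, " file(s) not found: ",
                 paste(missing, collapse = ", "))
        paths
    }
    if (identical(labelA, labelB))
        stop("group labels must differ")
    if (!is.null(enzymeDat) && !file.exists(enzymeDat))
        stop("enzyme flat file not found: ", enzymeDat)
    structure(list(groupA = expand(groupA, "A"),
                   groupB = expand(groupB, "B"),
                   labelA = labelA, labelB = labelB,
                   enzymeDat = enzymeDat, annotateMode = annotateMode,
                   substringFallback = isTRUE(substringFallback),
                   outPrefix = outPrefix,
                   skipBadFiles = isTRUE(skipBadFiles), seed = seed),
              class = "enzymomeRunConfig")
}

.readGroup <- function(paths, skipBad) {
    recs <- list()
    for (p in paths) {
        r <- tryCatch(readGenBank(p), error = function(e) {
            if (skipBad) {
                warning("skipping unreadable file ", p, ": ",
                        conditionMessage(e), call. = FALSE)
                NULL
            } else stop("failed to read ", p, ": ", conditionMessage(e),
                        call. = FALSE)
        })
        if (!is.null(r)) recs[[length(recs) + 1L]] <- r
    }
    recs
}

#' Run a full two-group comparison and write its reports
#'
#' Reads both groups of GenBank files, optionally annotates un-annotated
#' CDSs de novo against the ENZYME flat file, compares the two enzyme
#' complements, and writes three TSV files: `<outPrefix>.report.tsv` (the
#' three-section row-level report), `<outPrefix>.summary.tsv` (one line of
#' category counts) and `<outPrefix>.coverage.tsv` (per-genome coverage
#' statistics). Per-file annotation tallies are logged to stderr. Output is
#' deterministic: the same inputs and configuration give byte-identical
#' files.
#'
#' @param config a validated configuration from [newRunConfig()].
#' @return (invisibly) list with `result` ([ComparisonResult-class]),
#'   `coverage` (data.frame), `summaries` (per-genome annotation tallies)
#'   and `files` (paths written).
#' @export
runCompare <- function(config) {
    stopifnot(inherits(config, "enzymomeRunConfig"))
    db <- if (!is.null(config$enzymeDat)) readEnzymeDb(config$enzymeDat)
    origA <- .readGroup(config$groupA, config$skipBadFiles)
    origB <- .readGroup(config$groupB, config$skipBadFiles)
    if (!length(origA) || !length(origB))
        stop("a group is empty after reading; nothing to compare")

    annotate <- function(recs) {
        if (is.null(db) || config$annotateMode == "off")
            return(list(recs = recs, summaries = NULL))
        out <- lapply(recs, annotateGenome, db = db,
                      mode = config$annotateMode,
                      substring = config$substringFallback)
        summ <- do.call(rbind, c(lapply(out, `[[`, "summary"),
                                 make.row.names = FALSE))
        summ <- cbind(organism = vapply(recs, organismName, ""), summ)
        for (i in seq_len(nrow(summ)))
            message(sprintf(
                "[annotate] %s: %d CDSs, %d already annotated, %d de novo (%d multi-match)",
                summ$organism[i], summ$total_cds[i],
                summ$already_annotated[i], summ$newly_annotated[i],
                summ$multi_flagged[i]))
        list(recs = lapply(out, `[[`, "record"), summaries = summ)
    }
    annA <- annotate(origA)
    annB <- annotate(origB)

    result <- compareGroups(MicrobiomeGroup(config$labelA, annA$recs),
                            MicrobiomeGroup(config$labelB, annB$recs),
                            db = db)
    cov <- coverageTable(c(origA, origB), c(annA$recs, annB$recs))

    files <- paste0(config$outPrefix, c(".report.tsv", ".summary.tsv",
                                        ".coverage.tsv"))
    writeLines(renderReport(result, config = config[c(
        "labelA", "labelB", "annotateMode", "substringFallback")]),
        files[1], useBytes = FALSE)
    cnt <- comparisonCounts(result)
    writeLines(c(paste("identical", paste0("unique_", config$labelA),
                       paste0("unique_", config$labelB), sep = "\t"),
                 paste(cnt["identical"], cnt["unique_a"], cnt["unique_b"],
                       sep = "\t")), files[2])
    utils::write.table(formatCoverage(cov), files[3], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    message(sprintf("[compare] %s vs %s: %d identical, %d unique to %s, %d unique to %s (rows, gene copies included)",
                    config$labelA, config$labelB, cnt["identical"],
                    cnt["unique_a"], config$labelA,
                    cnt["unique_b"], config$labelB))
    invisible(list(result = result, coverage = cov,
                   summaries = rbind(annA$summaries, annB$summaries),
                   files = files))
}
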