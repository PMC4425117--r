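## GenBank flat-file I/O, scoped to what enzyme profiling needs: LOCUS
## records, the VERSION/GI field, the SOURCE organism, and CDS features with
## /product, /EC_number and /note qualifiers. Features are opaque annotation
## carriers; coordinates and sequence are never interpreted.

.NOTE_MULTI <- "multi-EC designation: ambiguous de novo annotation (low reliability)"
.NOTE_DENOVO <- "de novo EC annotation (product-name match)"

#' Construct a GenomeRecord in memory
#'
#' Convenience constructor used by the fixture generator and tests; files on
#' disk are read with [readGenBank()].
#'
#' @param giAccession GI identifier (numeric NCBI identifier as text).
#' @param organism organism name.
#' @param product character vector of CDS product names (`NA` allowed).
#' @param ecNumbers list of character vectors, one per CDS (default: none).
#' @param reliability integer vector of 0/1 flags (default all 1).
#' @param origin character vector, `"original"` or `"de_novo"`.
#' @param sourcePath optional path of the file the record derives from.
#' @return a [GenomeRecord-class] object.
#' @export
GenomeRecord <- function(giAccession, organism, product = character(),
                         ecNumbers = NULL, reliability = NULL,
                         origin = NULL, sourcePath = NA_character_) {
    n <- length(product)
    if (is.null(ecNumbers)) ecNumbers <- rep(list(character()), n)
    if (is.null(reliability)) reliability <- rep(1L, n)
    if (is.null(origin)) origin <- rep("original", n)
    cds <- data.frame(feature_index = seq_len(n),
                      product = as.character(product),
                      ec_numbers = I(ecNumbers),
                      reliability = as.integer(reliability),
                      origin = as.character(origin),
                      stringsAsFactors = FALSE)
    new("GenomeRecord", giAccession = as.character(giAccession),
        organism = organism, cds = cds,
        sourcePath = as.character(sourcePath))
}

#' @describeIn GenomeRecord the GI accession.
#' @param x a `GenomeRecord`.
#' @export
giAccession <- function(x) {
    stopifnot(is(x, "GenomeRecord"))
    x@giAccession
}

#' @describeIn GenomeRecord the organism name.
#' @export
organismName <- function(x) {
    stopifnot(is(x, "GenomeRecord"))
    x@organism
}

#' @describeIn GenomeRecord the CDS feature table (data.frame).
#' @export
cdsTable <- function(x) {
    stopifnot(is(x, "GenomeRecord"))
    x@cds
}

#' @describeIn GenomeRecord number of CDS features.
#' @export
totalCds <- function(x) {
    stopifnot(is(x, "GenomeRecord"))
    nrow(x@cds)
}

#' @rdname GenomeRecord-class
#' @param object a `GenomeRecord`.
#' @export
setMethod("show", "GenomeRecord", function(object) {
    cds <- object@cds
    cat("GenomeRecord:", object@organism,
        paste0("(GI ", object@giAccession, ")\n"))
    cat("  CDS features:", nrow(cds), "|",
        sum(lengths(cds$ec_numbers) > 0L), "with >=1 EC (",
        sum(cds$origin == "de_novo"), "de novo,",
        sum(cds$reliability == 0L), "low-reliability )\n")
})

## ---- parsing ----

# split a character vector of lines into LOCUS records (list of line
# vectors); the "//" terminators are dropped
.splitLocusRecords <- function(lines) {
    ends <- which(lines == "//")
    if (!length(ends)) {
        recs <- list(lines)
    } else {
        starts <- c(1L, head(ends, -1L) + 1L)
        recs <- mapply(function(s, e) lines[s:(e - 1L)],
                       starts, ends, SIMPLIFY = FALSE)
    }
    recs[vapply(recs, function(r) any(grepl("^LOCUS", r)), NA)]
}

# parse the FEATURES block of one LOCUS record into a list of features,
# each a list(key, location, qualifiers = named list of character values)
.parseFeatures <- function(rec) {
    fstart <- grep("^FEATURES", rec)
    if (!length(fstart)) return(list())
    fend <- grep("^(ORIGIN|CONTIG|BASE COUNT)", rec)
    fend <- if (length(fend)) min(fend[fend > fstart[1]]) - 1L else length(rec)
    if (fend <= fstart[1]) return(list())
    block <- rec[(fstart[1] + 1L):fend]
    block <- block[nzchar(trimws(block))]
    isKey <- grepl("^ {5}\\S", block) & !grepl("^ {21}", block)
    if (!any(isKey)) return(list())
    idx <- which(isKey)
    lapply(seq_along(idx), function(i) {
        from <- idx[i]
        to <- if (i < length(idx)) idx[i + 1L] - 1L else length(block)
        keyline <- block[from]
        key <- trimws(substr(keyline, 6L, 20L))
        loc <- trimws(substr(keyline, 21L, nchar(keyline)))
        quals <- list()
        cont <- block[seq.int(from + 1L, length.out = max(0L, to - from))]
        # location may continue before the first qualifier
        body <- trimws(cont)
        qstart <- grep("^/", body)
        if (length(qstart) && qstart[1] > 1L)
            loc <- paste0(loc, paste(body[seq_len(qstart[1] - 1L)],
                                     collapse = ""))
        if (length(qstart)) {
            qidx <- c(qstart, length(body) + 1L)
            for (q in seq_along(qstart)) {
                txt <- paste(body[qidx[q]:(qidx[q + 1L] - 1L)],
                             collapse = " ")
                m <- regmatches(txt, regexec("^/([A-Za-z0-9_]+)(=(.*))?$",
                                             txt))[[1]]
                if (!length(m)) next
                name <- m[2]
                val <- if (nzchar(m[3])) m[4] else ""
                val <- sub("^\"", "", val)
                val <- sub("\"$", "", val)
                quals[[length(quals) + 1L]] <- list(name = name, value = val)
            }
        }
        list(key = key, location = loc, qualifiers = quals)
    })
}

.qualValues <- function(feature, name) {
    vals <- vapply(feature$qualifiers, function(q)
        if (q$name == name) q$value else NA_character_, "")
    vals[!is.na(vals)]
}

#' Read a GenBank flat file into a GenomeRecord
#'
#' All CDS features across all LOCUS records in the file (chromosome plus
#' plasmid records) are concatenated into one [GenomeRecord-class], in file
#' order. `/product` and `/EC_number` qualifiers are captured; pre-existing
#' EC annotations get `origin = "original"` and `reliability = 1`. A CDS
#' carrying the machine-readable low-reliability designation written by
#' [writeGenBankAnnotations()] is restored as a de novo multi-match
#' (`reliability = 0`); one carrying the de novo note is restored as a
#' unique de novo assignment. The GI accession is taken from the first
#' `VERSION` line's `GI:` field (falling back to the accession, then the
#' LOCUS name), the organism from the first `ORGANISM` line.
#'
#' @param path path to a GenBank flat file.
#' @return a [GenomeRecord-class]; a file without CDS features yields a
#'   valid record with `totalCds(x) == 0` and a warning.
#' @export
readGenBank <- function(path) {
    lines <- readLines(path, warn = FALSE)
    recs <- .splitLocusRecords(lines)
    if (!length(recs)) stop("no LOCUS record found in ", path)

    first <- recs[[1]]
    gi <- NA_character_
    vline <- grep("^VERSION", first, value = TRUE)
    if (length(vline)) {
        m <- regmatches(vline[1], regexec("GI:([0-9]+)", vline[1]))[[1]]
        if (length(m)) gi <- m[2]
        else {
            tok <- strsplit(trimws(substr(vline[1], 13L, nchar(vline[1]))),
                            "[[:space:]]+")[[1]]
            if (length(tok)) gi <- tok[1]
        }
    }
    if (is.na(gi) || !nzchar(gi)) {
        lline <- grep("^LOCUS", first, value = TRUE)[1]
        gi <- strsplit(trimws(substr(lline, 13L, nchar(lline))),
                       "[[:space:]]+")[[1]][1]
    }
    oline <- grep("^ {2}ORGANISM", first, value = TRUE)
    org <- if (length(oline)) trimws(sub("^ {2}ORGANISM", "", oline[1]))
           else NA_character_

    feats <- unlist(lapply(recs, .parseFeatures), recursive = FALSE)
    cds <- Filter(function(f) f$key == "CDS", feats)
    if (!length(cds))
        warning("no CDS features in ", path, call. = FALSE)

    product <- vapply(cds, function(f) {
        p <- .qualValues(f, "product")
        if (length(p)) p[1] else NA_character_
    }, "")
    ecs <- lapply(cds, .qualValues, "EC_number")
    notes <- lapply(cds, .qualValues, "note")
    isMulti <- vapply(notes, function(n) any(grepl(.NOTE_MULTI, n,
                                                   fixed = TRUE)), NA)
    isDeNovo <- isMulti | vapply(notes, function(n)
        any(grepl(.NOTE_DENOVO, n, fixed = TRUE)), NA)
    hasEc <- lengths(ecs) > 0L

    GenomeRecord(giAccession = gi, organism = org, product = product,
                 ecNumbers = ecs,
                 reliability = ifelse(isMulti & hasEc, 0L, 1L),
                 origin = ifelse(isDeNovo & hasEc, "de_novo", "original"),
                 sourcePath = path)
}

#' Extract enzyme rows from a genome
#'
#' One row per (CDS, EC) pair: a CDS annotated with k EC numbers yields k
#' rows; a CDS without any yields none. Gene copies are *not* collapsed —
#' two CDSs annotated with the same EC yield two rows, which is what makes
#' the downstream match statistics count gene copies.
#'
#' @param record a [GenomeRecord-class].
#' @return data.frame with columns `gi_accession`, `organism`, `ec_number`,
#'   `reliability`.
#' @export
extractEnzymeRows <- function(record) {
    stopifnot(is(record, "GenomeRecord"))
    cds <- record@cds
    k <- lengths(cds$ec_numbers)
    data.frame(gi_accession = rep(record@giAccession, sum(k)),
               organism = rep(record@organism, sum(k)),
               ec_number = unlist(cds$ec_numbers, use.names = FALSE),
               reliability = rep(cds$reliability, k),
               stringsAsFactors = FALSE)
}

## locate CDS feature blocks (start/end line indices) in a raw GenBank file,
## in the same order readGenBank() parses them
.cdsBlockSpans <- function(lines) {
    ends <- which(lines == "//")
    starts <- c(1L, head(ends, -1L) + 1L)
    if (!length(ends)) { starts <- 1L; ends <- length(lines) + 1L }
    spans <- list()
    for (r in seq_along(starts)) {
        rng <- starts[r]:(ends[r] - 1L)
        rec <- lines[rng]
        fstart <- grep("^FEATURES", rec)
        if (!length(fstart)) next
        fend <- grep("^(ORIGIN|CONTIG|BASE COUNT)", rec)
        fend <- if (length(fend)) min(fend[fend > fstart[1]]) - 1L
                else length(rec)
        if (fend <= fstart[1]) next
        seg <- (fstart[1] + 1L):fend
        isKey <- grepl("^ {5}\\S", rec[seg]) & !grepl("^ {21}", rec[seg])
        idx <- seg[isKey]
        if (!length(idx)) next
        keys <- trimws(substr(rec[idx], 6L, 20L))
        bounds <- c(idx, fend + 1L)
        for (i in seq_along(idx)) {
            if (keys[i] != "CDS") next
            to <- bounds[i + 1L] - 1L
            # trim trailing blank lines inside the block
            while (to > idx[i] && !nzchar(trimws(rec[to]))) to <- to - 1L
            spans[[length(spans) + 1L]] <-
                c(from = rng[1] + idx[i] - 1L, to = rng[1] + to - 1L)
        }
    }
    spans
}

#' Write a GenBank file with de novo EC annotations inserted
#'
#' Splices the annotations held in `record` into the original file: every
#' CDS annotated de novo gains one `/EC_number` qualifier per assigned EC
#' (a multi-match carries at most three) plus a machine-readable `/note`
#' designation — the low-reliability designation for multi-matches, a de
#' novo marker for unique matches. Original lines, qualifiers and products
#' are untouched, so a record with no de novo annotations is written with
#' feature content byte-identical to the input, and re-reading the output
#' with [readGenBank()] reproduces `record` exactly.
#'
#' @param record a [GenomeRecord-class] derived from `originalPath` (same
#'   CDS features in the same order), typically via [annotateGenome()].
#' @param originalPath the GenBank file the record was read from.
#' @param outPath output file path.
#' @return `outPath`, invisibly.
#' @export
writeGenBankAnnotations <- function(record, originalPath, outPath) {
    stopifnot(is(record, "GenomeRecord"))
    lines <- readLines(originalPath, warn = FALSE)
    spans <- .cdsBlockSpans(lines)
    cds <- record@cds
    if (length(spans) != nrow(cds))
        stop("record does not derive from ", originalPath, ": ",
             nrow(cds), " CDS features vs ", length(spans), " in file")
    pad <- strrep(" ", 21L)
    insertions <- list()
    for (i in seq_len(nrow(cds))) {
        if (cds$origin[i] != "de_novo" || !length(cds$ec_numbers[[i]]))
            next
        newl <- paste0(pad, "/EC_number=\"", cds$ec_numbers[[i]], "\"")
        note <- if (cds$reliability[i] == 0L) .NOTE_MULTI else .NOTE_DENOVO
        newl <- c(newl, paste0(pad, "/note=\"", note, "\""))
        insertions[[length(insertions) + 1L]] <-
            list(after = spans[[i]]["to"], lines = newl)
    }
    if (length(insertions)) {
        # apply bottom-up so earlier indices stay valid
        ord <- order(vapply(insertions, function(x) x$after, 0),
                     decreasing = TRUE)
        for (ins in insertions[ord])
            lines <- append(lines, ins$lines, after = ins$after)
    }
    writeLines(lines, outPath)
    invisible(outPath)
}

#' Fetch a GenBank record from NCBI by accession or GI (network)
#'
#' Thin convenience wrapper around NCBI E-utilities `efetch`; off the
#' default analysis path and never used by the test suite. Requires network
#' access.
#'
#' @param accession accession or GI number.
#' @param destfile where to save the flat file.
#' @return `destfile`, invisibly.
#' @export
fetchGenBank <- function(accession, destfile) {
    url <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/",
                  "efetch.fcgi?db=nuccore&rettype=gbwithparts",
                  "&retmode=text&id=", accession)
    utils::download.file(url, destfile, quiet = TRUE)
    invisible(destfile)
}
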