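#' @import methods
NULL

.EC_PATTERN <- "^[0-9]+\\.[0-9]+\\.[0-9]+\\.([0-9]+|-)$"

.ENZYME_RECORD_COLS <- c("ec_number", "recommended_name", "alt_names",
                         "catalytic_activity", "status", "transfer_targets",
                         "partial")

.CDS_COLS <- c("feature_index", "product", "ec_numbers", "reliability",
               "origin")

#' EnzymeDb: parsed ENZYME nomenclature plus a searchable name index
#'
#' Holds one record per Enzyme Commission (EC) entry of an ENZYME flat file
#' (ExPASy `enzyme.dat` dialect) together with a name index mapping every
#' normalized recommended/alternative name of an *active* entry to the EC
#' number(s) carrying it. Transferred and deleted entries are retained in
#' the record table (so they can be reported on lookup) but never enter the
#' index.
#'
#' @slot records data.frame with one row per EC entry; columns
#'   `ec_number`, `recommended_name`, `catalytic_activity`, `status`
#'   (character), `alt_names` and `transfer_targets` (list columns of
#'   character vectors) and `partial` (logical; `TRUE` for preliminary
#'   identifiers ending in `-`).
#' @slot index named list; names are normalized enzyme names, values are
#'   character vectors of EC numbers in ascending EC order.
#' @slot normalization identifier of the name-normalization rule applied to
#'   the index keys.
#'
#' @seealso [readEnzymeDb()], [parseEnzymeDat()], [buildNameIndex()],
#'   [lookupEc()]
#' @export
setClass("EnzymeDb",
         representation(records = "data.frame",
                        index = "list",
                        normalization = "character"))

setValidity("EnzymeDb", function(object) {
    msg <- character()
    rec <- object@records
    if (!all(.ENZYME_RECORD_COLS %in% names(rec)))
        msg <- c(msg, paste("records must have columns:",
                            paste(.ENZYME_RECORD_COLS, collapse = ", ")))
    else {
        bad <- !grepl(.EC_PATTERN, rec$ec_number)
        if (any(bad))
            msg <- c(msg, paste("malformed EC number(s):",
                                paste(rec$ec_number[bad], collapse = ", ")))
        if (!all(rec$status %in% c("active", "transferred", "deleted")))
            msg <- c(msg, "status must be active, transferred or deleted")
        noname <- rec$status == "active" & !nzchar(rec$recommended_name)
        if (any(noname))
            msg <- c(msg, "active records must have a recommended name")
        inactive <- rec$ec_number[rec$status != "active"]
        if (any(unlist(object@index) %in% inactive))
            msg <- c(msg, "index contains a transferred or deleted EC")
    }
    if (length(object@index)) {
        keys <- names(object@index)
        if (is.null(keys) || any(!nzchar(keys)))
            msg <- c(msg, "index keys must be non-empty names")
        else if (!identical(keys, vapply(keys, normalizeEnzymeName, "",
                                         USE.NAMES = FALSE)))
            msg <- c(msg, "index keys must already be normalized")
    }
    if (length(msg)) msg else TRUE
})

#' GenomeRecord: one organism's coding sequences and enzyme annotations
#'
#' A flattened view of one GenBank flat file: all CDS features across all
#' LOCUS records of the file (chromosome plus any plasmids), each carrying
#' its product name, its EC numbers and a binary reliability flag.
#'
#' @slot giAccession character(1); numeric NCBI GI identifier as text.
#' @slot organism character(1); organism name from the first SOURCE block.
#' @slot cds data.frame with one row per CDS feature: `feature_index`
#'   (integer ordinal), `product` (character, `NA` when absent),
#'   `ec_numbers` (list column of character vectors, possibly empty),
#'   `reliability` (integer, 0 or 1) and `origin` (`"original"` or
#'   `"de_novo"`).
#' @slot sourcePath character(1); path the record was read from (`NA` for
#'   records built in memory).
#'
#' @seealso [readGenBank()], [extractEnzymeRows()], [annotateGenome()]
#' @export
setClass("GenomeRecord",
         representation(giAccession = "character",
                        organism = "character",
                        cds = "data.frame",
                        sourcePath = "character"))

setValidity("GenomeRecord", function(object) {
    msg <- character()
    if (length(object@giAccession) != 1L || !nzchar(object@giAccession) ||
        is.na(object@giAccession))
        msg <- c(msg, "giAccession must be a single non-empty string")
    if (length(object@organism) != 1L)
        msg <- c(msg, "organism must be a single string")
    cds <- object@cds
    if (!all(.CDS_COLS %in% names(cds)))
        msg <- c(msg, paste("cds must have columns:",
                            paste(.CDS_COLS, collapse = ", ")))
    else if (nrow(cds)) {
        if (!all(cds$reliability %in% c(0L, 1L)))
            msg <- c(msg, "reliability must be 0 or 1")
        if (!all(cds$origin %in% c("original", "de_novo")))
            msg <- c(msg, "origin must be original or de_novo")
        # reliability 0 is reserved for ambiguous de novo assignments
        bad <- cds$reliability == 0L &
            (cds$origin != "de_novo" | !lengths(cds$ec_numbers))
        if (any(bad))
            msg <- c(msg, "reliability 0 requires a de novo multi-match")
    }
    if (length(msg)) msg else TRUE
})

#' MicrobiomeGroup: a labelled set of genomes forming one artificial
#' metagenome
#'
#' @slot label character(1); group label shown in reports (defaults used by
#'   [compareGroups()] are "Microbiome 1" / "Microbiome 2").
#' @slot genomes list of [GenomeRecord-class] objects.
#'
#' @seealso [compareGroups()], [groupRows()]
#' @export
setClass("MicrobiomeGroup",
         representation(label = "character", genomes = "list"))

setValidity("MicrobiomeGroup", function(object) {
    msg <- character()
    if (length(object@label) != 1L || !nzchar(object@label))
        msg <- c(msg, "label must be a single non-empty string")
    if (!all(vapply(object@genomes, is, NA, "GenomeRecord")))
        msg <- c(msg, "genomes must all be GenomeRecord objects")
    if (length(msg)) msg else TRUE
})

#' ComparisonResult: three-section classification of two enzyme complements
#'
#' Every enzyme row — one (CDS, EC) pair, gene copies *not* collapsed — of
#' both groups is placed in exactly one section: `identical` (the EC occurs
#' in both groups), `unique_a` or `unique_b`. Counts are row counts, so
#' multi-copy genes inflate them, as in the match statistics this mirrors.
#'
#' @slot rows data.frame with columns `section`, `gi_accession`, `organism`,
#'   `ec_number`, `ec_name`, `biochemistry`, `reliability`, `microbiome`;
#'   ordered by section, then EC number, organism and GI.
#' @slot counts named integer(3): `identical`, `unique_a`, `unique_b`.
#' @slot labels character(2): the two group labels (A then B).
#'
#' @seealso [compareGroups()], [comparisonRows()], [comparisonCounts()],
#'   [renderReport()]
#' @export
setClass("ComparisonResult",
         representation(rows = "data.frame",
                        counts = "integer",
                        labels = "character"))

setValidity("ComparisonResult", function(object) {
    msg <- character()
    if (!identical(names(object@counts),
                   c("identical", "unique_a", "unique_b")))
        msg <- c(msg, "counts must be named identical, unique_a, unique_b")
    if (length(object@labels) != 2L || object@labels[1] == object@labels[2])
        msg <- c(msg, "labels must be two distinct group labels")
    rows <- object@rows
    need <- c("section", "gi_accession", "organism", "ec_number", "ec_name",
              "biochemistry", "reliability", "microbiome")
    if (!all(need %in% names(rows)))
        msg <- c(msg, paste("rows must have columns:",
                            paste(need, collapse = ", ")))
    else {
        if (!all(rows$section %in% c("identical", "unique_a", "unique_b")))
            msg <- c(msg, "unknown section label")
        tab <- table(factor(rows$section,
                            c("identical", "unique_a", "unique_b")))
        if (!identical(as.integer(tab), unname(object@counts)))
            msg <- c(msg, "counts do not match section row tallies")
        # the EC sets underlying the three sections must be pairwise disjoint
        ecs <- split(rows$ec_number, rows$section)
        if (length(intersect(ecs$identical, c(ecs$unique_a, ecs$unique_b))) ||
            length(intersect(ecs$unique_a, ecs$unique_b)))
            msg <- c(msg, "section EC sets are not disjoint")
    }
    if (length(msg)) msg else TRUE
})
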