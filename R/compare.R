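#' Construct a labelled microbiome group
#'
#' @param label group label shown in reports ("Microbiome 1"/"Microbiome 2"
#'   by convention, or a custom name such as "control"/"autism").
#' @param genomes list of [GenomeRecord-class] objects.
#' @return a [MicrobiomeGroup-class].
#' @export
MicrobiomeGroup <- function(label, genomes) {
    if (is(genomes, "GenomeRecord")) genomes <- list(genomes)
    new("MicrobiomeGroup", label = label, genomes = genomes)
}

#' @describeIn MicrobiomeGroup the group label.
#' @param x a `MicrobiomeGroup`.
#' @export
groupLabel <- function(x) {
    stopifnot(is(x, "MicrobiomeGroup"))
    x@label
}

#' @describeIn MicrobiomeGroup the list of genomes.
#' @export
groupGenomes <- function(x) {
    stopifnot(is(x, "MicrobiomeGroup"))
    x@genomes
}

#' @describeIn MicrobiomeGroup all enzyme rows of the group — the
#'   concatenation of [extractEnzymeRows()] over its genomes.
#' @export
groupRows <- function(x) {
    stopifnot(is(x, "MicrobiomeGroup"))
    do.call(rbind, c(lapply(x@genomes, extractEnzymeRows),
                     make.row.names = FALSE))
}

#' @rdname MicrobiomeGroup-class
#' @param object a `MicrobiomeGroup`.
#' @export
setMethod("show", "MicrobiomeGroup", function(object) {
    cat("MicrobiomeGroup \"", object@label, "\": ",
        length(object@genomes), " genome(s), ",
        nrow(groupRows(object)), " enzyme rows\n", sep = "")
})

.lookupColumns <- function(db, ecs, sentinel = "unresolved") {
    if (is.null(db) || !length(ecs))
        return(data.frame(ec_name = rep(sentinel, length(ecs)),
                          biochemistry = rep(sentinel, length(ecs)),
                          stringsAsFactors = FALSE))
    uq <- unique(ecs)
    info <- lapply(uq, function(e) lookupEc(db, e))
    nm <- vapply(info, function(r)
        if (r$found && nzchar(r$recommended_name)) r$recommended_name
        else sentinel, "")
    bio <- vapply(info, function(r)
        if (r$found && nzchar(r$catalytic_activity)) r$catalytic_activity
        else sentinel, "")
    i <- match(ecs, uq)
    data.frame(ec_name = nm[i], biochemistry = bio[i],
               stringsAsFactors = FALSE)
}

#' Compare the enzyme complements of two microbiome groups
#'
#' Classifies every enzyme row — one (CDS, EC) pair, gene copies included —
#' of both groups into three sections. Identity is by EC-number string
#' equality only: an EC is *identical* when at least one row in each group
#' carries it, *unique* to a group when only that group's rows carry it.
#' Partial identifiers (`n.n.n.-`) compare as literal strings. Counts are
#' row counts, so multi-copy genes inflate them. Low-reliability rows
#' participate fully and carry their flag into the report.
#'
#' @param a,b [MicrobiomeGroup-class] objects with distinct labels.
#' @param db optional [EnzymeDb-class] used to fill the `ec_name` (the
#'   predominant name) and `biochemistry` report columns; ECs it cannot
#'   resolve get the `sentinel` text.
#' @param sentinel text used for unresolved report columns.
#' @return a [ComparisonResult-class]; rows ordered by section, EC number,
#'   organism, GI.
#' @export
compareGroups <- function(a, b, db = NULL, sentinel = "unresolved") {
    stopifnot(is(a, "MicrobiomeGroup"), is(b, "MicrobiomeGroup"))
    if (identical(a@label, b@label))
        stop("the two groups must have distinct labels (both are \"",
             a@label, "\")")
    if (!length(a@genomes) || !length(b@genomes))
        stop("both groups must contain at least one genome")
    ra <- groupRows(a)
    rb <- groupRows(b)
    ra$microbiome <- rep(a@label, nrow(ra))
    rb$microbiome <- rep(b@label, nrow(rb))
    inA <- unique(ra$ec_number)
    inB <- unique(rb$ec_number)
    both <- intersect(inA, inB)
    rows <- rbind(ra, rb)
    rows$section <- ifelse(rows$ec_number %in% both, "identical",
                           ifelse(rows$microbiome == a@label,
                                  "unique_a", "unique_b"))
    look <- .lookupColumns(db, rows$ec_number, sentinel)
    rows$ec_name <- look$ec_name
    rows$biochemistry <- look$biochemistry
    rows <- rows[, c("section", "gi_accession", "organism", "ec_number",
                     "ec_name", "biochemistry", "reliability",
                     "microbiome")]
    key <- numeric(nrow(rows))
    key[orderEc(rows$ec_number)] <- seq_len(nrow(rows))
    o <- order(match(rows$section, c("identical", "unique_a", "unique_b")),
               key, rows$organism, rows$gi_accession)
    rows <- rows[o, , drop = FALSE]
    rownames(rows) <- NULL
    counts <- table(factor(rows$section,
                           c("identical", "unique_a", "unique_b")))
    new("ComparisonResult", rows = rows,
        counts = stats::setNames(as.integer(counts),
                                 c("identical", "unique_a", "unique_b")),
        labels = c(a@label, b@label))
}

#' @rdname ComparisonResult-class
#' @details `comparisonRows(x)`: the classified rows (data.frame), all
#'   sections; filter on the `section` column for one section.
#' @param x a `ComparisonResult`.
#' @export
comparisonRows <- function(x) {
    stopifnot(is(x, "ComparisonResult"))
    x@rows
}

#' @rdname ComparisonResult-class
#' @details `comparisonCounts(x)`: named row counts
#'   (`identical`/`unique_a`/`unique_b`), gene copies included.
#' @export
comparisonCounts <- function(x) {
    stopifnot(is(x, "ComparisonResult"))
    x@counts
}

#' @rdname ComparisonResult-class
#' @details `comparisonLabels(x)`: the two group labels (A then B).
#' @export
comparisonLabels <- function(x) {
    stopifnot(is(x, "ComparisonResult"))
    x@labels
}

#' @rdname ComparisonResult-class
#' @param object a `ComparisonResult`.
#' @export
setMethod("show", "ComparisonResult", function(object) {
    cat("ComparisonResult:", object@labels[1], "vs", object@labels[2], "\n")
    cat("  identical:", object@counts["identical"],
        "| unique to", paste0(object@labels[1], ":"),
        object@counts["unique_a"],
        "| unique to", paste0(object@labels[2], ":"),
        object@counts["unique_b"], "(rows; gene copies included)\n")
})

#' Collapse section rows to display rows with gene-copy notation
#'
#' Rows sharing (EC, GI, organism) within one section collapse to a single
#' display row whose organism text carries a "(×n)" suffix when n ≥ 2 gene
#' copies are present. [expandMultiplicity()] inverts the collapse.
#'
#' @param rows data.frame of rows from one section of a
#'   [ComparisonResult-class] (needs `ec_number`, `gi_accession`,
#'   `organism` columns).
#' @return data.frame with columns `ec_number`, `gi_accession`, `organism`,
#'   `n_copies`, `display`; ordered by EC then organism.
#' @export
groupWithMultiplicity <- function(rows) {
    if (!nrow(rows))
        return(data.frame(ec_number = character(),
                          gi_accession = character(),
                          organism = character(), n_copies = integer(),
                          display = character(), stringsAsFactors = FALSE))
    key <- paste(rows$ec_number, rows$gi_accession, rows$organism,
                 sep = "\r")
    tab <- table(key)
    uq <- rows[!duplicated(key), c("ec_number", "gi_accession", "organism")]
    uq$n_copies <- as.integer(tab[paste(uq$ec_number, uq$gi_accession,
                                        uq$organism, sep = "\r")])
    uq$display <- ifelse(uq$n_copies >= 2L,
                         sprintf("%s (×%d)", uq$organism, uq$n_copies),
                         uq$organism)
    ekey <- numeric(nrow(uq))
    ekey[orderEc(uq$ec_number)] <- seq_len(nrow(uq))
    uq <- uq[order(ekey, uq$organism, uq$gi_accession), , drop = FALSE]
    rownames(uq) <- NULL
    uq
}

#' @rdname groupWithMultiplicity
#' @param display a data.frame from [groupWithMultiplicity()].
#' @return for `expandMultiplicity`: the row-level data.frame (one row per
#'   gene copy) whose multiset of (EC, GI, organism) equals the input to
#'   [groupWithMultiplicity()].
#' @export
expandMultiplicity <- function(display) {
    i <- rep(seq_len(nrow(display)), display$n_copies)
    out <- display[i, c("ec_number", "gi_accession", "organism"),
                   drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Difference in match statistics between two comparison runs
#'
#' Componentwise signed difference `later - earlier` of the three category
#' counts, used to approximate how many *new* unique results a later, larger
#' query contributed relative to an earlier one.
#'
#' @param later,earlier numeric vectors of three counts (identical,
#'   unique_a, unique_b) or [ComparisonResult-class] objects.
#' @return named numeric(3) of signed deltas.
#' @export
statsDiff <- function(later, earlier) {
    cnt <- function(x) {
        if (is(x, "ComparisonResult")) x <- comparisonCounts(x)
        stopifnot(length(x) == 3L, is.numeric(x))
        unname(x)
    }
    stats::setNames(cnt(later) - cnt(earlier),
                    c("identical", "unique_a", "unique_b"))
}
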