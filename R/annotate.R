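## De novo EC annotation by product-name matching. A lookup of one product
## name against the name index has exactly three possible outcomes: no
## match, one unique match, or more than one match. Unique matches (and
## annotations already present in the source file) are reliability 1;
## multi-matches are recorded with their first three candidate ECs in
## ascending order and flagged reliability 0 pending manual curation.

#' Match one product name against the enzyme name index
#'
#' The product name is normalized ([normalizeEnzymeName()]) and looked up
#' exactly. If that yields nothing and `substring = TRUE`, a fallback pass
#' accepts index keys that contain the product (or are contained in it) as
#' a substring — product strings often carry strain- or locus-specific
#' suffixes. The same EC reachable through both a recommended and an
#' alternative name counts once.
#'
#' @param product non-empty product name.
#' @param db an [EnzymeDb-class].
#' @param substring enable the substring fallback pass (default off; exact
#'   matching is conservative and reproducible).
#' @return list with elements `outcome` (`"none"`, `"unique"` or
#'   `"multiple"`), `assigned_ecs` (character; empty, one, or the first
#'   three candidates in ascending EC order), `reliability` (1 for none or
#'   unique, 0 for multiple) and `match_stage` (`"exact"`, `"substring"`,
#'   or `NA` when nothing matched).
#' @export
matchProduct <- function(product, db, substring = FALSE) {
    stopifnot(is(db, "EnzymeDb"), length(product) == 1L, nzchar(product))
    key <- normalizeEnzymeName(product)
    idx <- nameIndex(db)
    ecs <- idx[[key]]
    stage <- if (length(ecs)) "exact" else NA_character_
    if (!length(ecs) && substring && nzchar(key)) {
        keys <- names(idx)
        hit <- vapply(keys, function(k)
            grepl(key, k, fixed = TRUE) || grepl(k, key, fixed = TRUE),
            NA, USE.NAMES = FALSE)
        if (any(hit)) {
            ecs <- sortEc(unique(unlist(idx[hit], use.names = FALSE)))
            stage <- "substring"
        }
    }
    if (is.null(ecs)) ecs <- character()
    if (!length(ecs))
        list(outcome = "none", assigned_ecs = character(),
             reliability = 1L, match_stage = NA_character_)
    else if (length(ecs) == 1L)
        list(outcome = "unique", assigned_ecs = ecs,
             reliability = 1L, match_stage = stage)
    else
        list(outcome = "multiple", assigned_ecs = head(sortEc(ecs), 3L),
             reliability = 0L, match_stage = stage)
}

#' Annotate a genome's un-annotated CDSs de novo
#'
#' Only CDSs with an empty EC set (and a product name) are matched against
#' the index; annotations already present — original or from an earlier
#' pass — are never altered, so the operation is idempotent. Under mode
#' `"unique+multi"` a unique match writes its EC with reliability 1 and a
#' multi-match writes its first three candidates with reliability 0; under
#' `"unique-only"` multi-matches are left untouched (but still tallied);
#' `"off"` performs no matching at all.
#'
#' @param record a [GenomeRecord-class].
#' @param db an [EnzymeDb-class].
#' @param mode annotation mode: `"unique+multi"` (default), `"unique-only"`
#'   or `"off"`.
#' @param substring enable the substring fallback of [matchProduct()].
#' @return list with elements `record` (the annotated [GenomeRecord-class])
#'   and `summary`, a one-row data.frame with `total_cds`,
#'   `already_annotated`, `newly_annotated`, `multi_flagged` (CDSs whose
#'   product matched more than one EC, whether or not the mode wrote them)
#'   and `untouched` (`already + newly + untouched == total`).
#' @export
annotateGenome <- function(record, db,
                           mode = c("unique+multi", "unique-only", "off"),
                           substring = FALSE) {
    stopifnot(is(record, "GenomeRecord"), is(db, "EnzymeDb"))
    mode <- match.arg(mode)
    cds <- record@cds
    already <- sum(lengths(cds$ec_numbers) > 0L)
    newly <- 0L
    multi <- 0L
    if (mode != "off") {
        todo <- which(lengths(cds$ec_numbers) == 0L & !is.na(cds$product) &
                      nzchar(cds$product))
        for (i in todo) {
            m <- matchProduct(cds$product[i], db, substring = substring)
            # multi-matches are tallied even when the mode leaves them
            # unwritten, so the ambiguity burden is always visible
            if (m$outcome == "multiple") multi <- multi + 1L
            if (m$outcome == "unique" ||
                (m$outcome == "multiple" && mode == "unique+multi")) {
                cds$ec_numbers[[i]] <- m$assigned_ecs
                cds$reliability[i] <- m$reliability
                cds$origin[i] <- "de_novo"
                newly <- newly + 1L
            }
        }
    }
    out <- record
    out@cds <- cds
    validObject(out)
    summary <- data.frame(total_cds = nrow(cds),
                          already_annotated = already,
                          newly_annotated = newly,
                          multi_flagged = multi,
                          untouched = nrow(cds) - already - newly)
    list(record = out, summary = summary)
}
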