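## Synthetic fixtures with known ground truth: miniature ENZYME flat files
## and GenBank genome files whose planted enzyme inventories fully determine
## the expected comparison counts. Nucleotide sequences are random ACGT
## filler of minimal length; the features carry all the semantic load, since
## no analysis stage reads sequence content.

#' Default enzyme entries for fixture generation
#'
#' A curated set of enzyme nomenclature entries centred on gut-microbiome
#' metabolism — glutamate, transsulfuration/transmethylation, antioxidant
#' and dehalogenase chemistry — with recommended names, selected alternative
#' names and catalytic activities, plus bookkeeping entries exercising every
#' parser branch: one transferred entry, one deleted entry and two
#' *synthetic* alcohol-dehydrogenase entries sharing a planted alternative
#' name so that name collisions (multi-match outcomes) are always present.
#'
#' @return data.frame with columns `ec` (character), `name` (character),
#'   `alt` (list of character vectors), `activity` (character), `status`
#'   (character) and `targets` (list; transfer targets).
#' @export
defaultEnzymeEntries <- function() {
    e <- function(ec, name, activity, alt = character(),
                  status = "active", targets = character())
        list(ec = ec, name = name, alt = alt, activity = activity,
             status = status, targets = targets)
    entries <- list(
        e("2.6.1.11", "Acetylornithine transaminase",
          "N(2)-acetyl-l-ornithine + 2-oxoglutarate = N-acetyl-l-glutamate 5-semialdehyde + l-glutamate",
          c("Acetylornithine aminotransferase")),
        e("2.6.1.52", "Phosphoserine transaminase",
          "(1) O-phospho-l-serine + 2-oxoglutarate = 3-phosphonooxypyruvate + l-glutamate. (2) 4-phosphonooxy-l-threonine + 2-oxoglutarate = (3R)-3-hydroxy-2-oxo-4-phosphonooxybutanoate + l-glutamate"),
        e("1.2.7.3", "2-oxoglutarate synthase",
          "2-oxoglutarate + CoA + 2 oxidized ferredoxin = succinyl-CoA + CO(2) + 2 reduced ferredoxin + 2 H(+)",
          c("2-ketoglutarate ferredoxin oxidoreductase")),
        e("1.4.1.14", "Glutamate synthase (NADH)",
          "2 l-glutamate + NAD(+) = l-glutamine + 2-oxoglutarate + NADH"),
        e("2.1.1.10", "Homocysteine S-methyltransferase",
          "S-methyl-l-methionine + l-homocysteine = 2 l-methionine"),
        e("2.1.1.14", "5-methyltetrahydropteroyltriglutamate--homocysteine S-methyltransferase",
          "5-methyltetrahydropteroyltri-l-glutamate + l-homocysteine = tetrahydropteroyltri-l-glutamate + l-methionine"),
        e("3.5.3.1", "Arginase",
          "l-arginine + H2O = l-ornithine + urea",
          c("Arginine amidinase")),
        e("4.2.1.22", "Cystathionine beta-synthase",
          "l-serine + l-homocysteine = l-cystathionine + H2O",
          c("Serine sulfhydrase")),
        e("4.4.1.1", "Cystathionine gamma-lyase",
          "l-cystathionine + H2O = l-cysteine + NH3 + 2-oxobutanoate",
          c("Gamma-cystathionase")),
        e("1.16.1.1", "Mercury(II) reductase",
          "Hg + NADP(+) + H(+) = Hg(2+) + NADPH"),
        e("2.1.1.176", "16S rRNA (cytosine(967)-C(5))-methyltransferase",
          "S-adenosyl-l-methionine + cytosine(967) in 16S rRNA = S-adenosyl-l-homocysteine + 5-methylcytosine(967) in 16S rRNA"),
        e("1.11.1.1", "NADH peroxidase",
          "NADH + H2O2 = NAD(+) + 2 H2O"),
        e("1.15.1.2", "Superoxide reductase",
          "reduced rubredoxin + superoxide + 2 H(+) = rubredoxin + H2O2"),
        e("1.11.1.9", "Glutathione peroxidase",
          "2 glutathione + H2O2 = glutathione disulfide + 2 H2O"),
        e("4.1.1.50", "Adenosylmethionine decarboxylase",
          "S-adenosyl-l-methionine = S-adenosyl 3-(methylthio)propylamine + CO2"),
        e("4.1.1.22", "Histidine decarboxylase",
          "l-histidine = histamine + CO2"),
        e("6.3.2.2", "Glutamate–cysteine ligase",
          "ATP + l-glutamate + l-cysteine = ADP + phosphate + gamma-l-glutamyl-l-cysteine",
          c("Gamma-glutamylcysteine synthetase")),
        e("6.3.2.3", "Glutathione synthase",
          "ATP + gamma-l-glutamyl-l-cysteine + glycine = ADP + phosphate + glutathione",
          c("Glutathione synthetase")),
        e("2.6.1.44", "Alanine--glyoxylate transaminase",
          "l-alanine + glyoxylate = pyruvate + glycine"),
        e("1.8.99.3", "Hydrogen sulfite reductase",
          "(O3S.S.SO3)(2-) + acceptor + 2 H2O + OH(-) = 3 HSO3(-) + reduced acceptor"),
        e("4.4.1.11", "Methionine gamma-lyase",
          "l-methionine + H2O = methanethiol + NH3 + 2-oxobutanoate"),
        e("1.8.1.2", "Sulfite reductase (NADPH)",
          "H2S + 3 NADP(+) + 3 H2O = sulfite + 3 NADPH"),
        e("5.4.3.5", "D-ornithine 4,5-aminomutase",
          "d-ornithine = (2R,4S)-2,4-diaminopentanoate"),
        e("5.1.1.12", "Ornithine racemase",
          "l-ornithine = d-ornithine"),
        e("2.1.1.77", "Protein-l-isoaspartate (d-aspartate) O-methyltransferase",
          "S-adenosyl-l-methionine + protein l-isoaspartate = S-adenosyl-l-homocysteine + protein l-isoaspartate alpha-methyl ester"),
        e("2.8.1.2", "3-mercaptopyruvate sulfurtransferase",
          "3-mercaptopyruvate + cyanide = pyruvate + thiocyanate"),
        e("2.8.1.1", "Thiosulfate sulfurtransferase",
          "thiosulfate + cyanide = sulfite + thiocyanate",
          c("Rhodanese")),
        e("4.4.1.8", "Cystathionine beta-lyase",
          "l-cystathionine + H2O = l-homocysteine + NH3 + pyruvate",
          c("Beta-cystathionase")),
        e("3.8.1.9", "(R)-2-haloacid dehalogenase",
          "(R)-2-haloacid + H2O = (S)-2-hydroxyacid + halide"),
        e("3.8.1.2", "(S)-2-haloacid dehalogenase",
          "(S)-2-haloacid + H2O = (R)-2-hydroxyacid + halide"),
        e("3.8.1.10", "2-haloacid dehalogenase (configuration-inverting)",
          "(1) (S)-2-haloacid + H2O = (R)-2-hydroxyacid + halide. (2) (R)-2-haloacid + H2O = (S)-2-hydroxyacid + halide"),
        e("3.8.1.5", "Haloalkane dehalogenase",
          "1-haloalkane + H2O = a primary alcohol + halide"),
        # synthetic collision pair: both carry the same alternative name so
        # fixture indexes always contain a multi-valued key
        e("1.1.1.1", "Alcohol dehydrogenase",
          "a primary alcohol + NAD(+) = an aldehyde + NADH",
          c("Alcohol dehydrogenase (acceptor)")),
        e("1.1.1.2", "Alcohol dehydrogenase (NADP(+))",
          "a primary alcohol + NADP(+) = an aldehyde + NADPH",
          c("Alcohol dehydrogenase (acceptor)")),
        e("1.1.1.5", "", "", status = "transferred",
          targets = c("1.1.1.303", "1.1.1.304")),
        e("1.1.1.74", "", "", status = "deleted"))
    data.frame(ec = vapply(entries, `[[`, "", "ec"),
               name = vapply(entries, `[[`, "", "name"),
               alt = I(lapply(entries, `[[`, "alt")),
               activity = vapply(entries, `[[`, "", "activity"),
               status = vapply(entries, `[[`, "", "status"),
               targets = I(lapply(entries, `[[`, "targets")),
               stringsAsFactors = FALSE)
}

.entriesToRecords <- function(entries) {
    data.frame(ec_number = entries$ec,
               recommended_name = entries$name,
               alt_names = I(entries$alt),
               catalytic_activity = entries$activity,
               status = entries$status,
               transfer_targets = I(entries$targets),
               partial = grepl("-$", entries$ec),
               stringsAsFactors = FALSE)
}

#' Write a miniature ENZYME flat file with known ground truth
#'
#' @param path output file path.
#' @param entries entry table as from [defaultEnzymeEntries()] (a zero-row
#'   table yields a file with no records).
#' @return (invisibly) list with `path` and `records`, the ground-truth
#'   enzyme record table constructed directly from `entries` (not by
#'   parsing the file).
#' @export
makeEnzymeDat <- function(path, entries = defaultEnzymeEntries()) {
    records <- .entriesToRecords(entries)
    writeEnzymeDat(records, path)
    invisible(list(path = path, records = records))
}

## ---- GenBank fixture text ----

.randomSeq <- function(n) paste(sample(c("a", "c", "g", "t"), n,
                                       replace = TRUE), collapse = "")

.originLines <- function(seq) {
    n <- nchar(seq)
    starts <- seq.int(1L, n, by = 60L)
    vapply(starts, function(s) {
        chunk <- substr(seq, s, min(s + 59L, n))
        tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                          pmin(seq(10L, nchar(chunk) + 9L, 10L),
                               nchar(chunk)))
        sprintf("%9d %s", s, paste(tens, collapse = " "))
    }, "")
}

# one LOCUS record; cdsList: list of list(product=, ecs=character())
.locusText <- function(name, organism, gi, cdsList, accession = name) {
    len <- max(100L, 90L * length(cdsList) + 10L)
    pad <- strrep(" ", 21L)
    out <- c(
        sprintf("LOCUS       %-16s %11d bp    DNA     circular BCT 01-JAN-2015",
                name, len),
        sprintf("DEFINITION  %s, synthetic fixture genome.", organism),
        sprintf("ACCESSION   %s", accession),
        sprintf("VERSION     %s.1  GI:%s", accession, gi),
        sprintf("SOURCE      %s", organism),
        sprintf("  ORGANISM  %s", organism),
        "            Bacteria.",
        "FEATURES             Location/Qualifiers",
        sprintf("     source          1..%d", len),
        paste0(pad, sprintf("/organism=\"%s\"", organism)),
        paste0(pad, "/mol_type=\"genomic DNA\""))
    for (i in seq_along(cdsList)) {
        cds <- cdsList[[i]]
        from <- (i - 1L) * 90L + 1L
        out <- c(out, sprintf("     CDS             %d..%d", from,
                              from + 89L))
        if (!is.null(cds$product) && !is.na(cds$product))
            out <- c(out, paste0(pad, sprintf("/product=\"%s\"",
                                              cds$product)))
        for (ec in cds$ecs)
            out <- c(out, paste0(pad, sprintf("/EC_number=\"%s\"", ec)))
    }
    c(out, "ORIGIN", .originLines(.randomSeq(len)), "//")
}

#' Specification of a synthetic microbiome pair
#'
#' Describes two groups of genomes by their planted enzyme inventories. Each
#' genome spec lists: pre-annotated ECs with gene-copy numbers (`planted`, a
#' named integer vector EC -> copies, written as `/product` + `/EC_number`),
#' ECs present only as a matchable product name (`productOnly`, resolved by
#' de novo annotation), the number of CDSs carrying the planted ambiguous
#' (collision) product name (`ambiguous`), and the genome's total CDS count
#' (`nCds`; the remainder are "hypothetical protein" filler).
#'
#' The default emulates the study conditions at reduced scale: two groups of
#' six genomes (a reduced control-vs-autism comparison), 60 CDSs per genome,
#' original EC coverage inside the 12--25 percent band reported as "good",
#' multi-copy genes up to x5, two product-only CDSs and one ambiguous CDS
#' per genome.
#'
#' @param labelA,labelB group labels.
#' @return a list with elements `labelA`, `labelB`, `groupA`, `groupB`
#'   (lists of genome specs) and `collisionName` (the shared alternative
#'   name of the planted collision entries).
#' @export
defaultFixtureSpec <- function(labelA = "control", labelB = "autism") {
    entries <- defaultEnzymeEntries()
    act <- entries$ec[entries$status == "active" &
                      entries$ec != "1.1.1.1" & entries$ec != "1.1.1.2"]
    g <- function(organism, gi, planted, productOnly = character(),
                  ambiguous = 1L, nCds = 60L)
        list(organism = organism, gi = gi, planted = planted,
             productOnly = productOnly, ambiguous = ambiguous, nCds = nCds)
    # shared core present in every genome of both groups
    core <- stats::setNames(rep(1L, 4), act[1:4])
    groupA <- list(
        g("Synthetica communis A1", "900000001",
          c(core, stats::setNames(c(5L, 2L), act[5:6]))),
        g("Synthetica communis A2", "900000002",
          c(core, stats::setNames(1L, act[7])),
          productOnly = act[8]),
        g("Synthetica vulgaris A3", "900000003",
          c(core, stats::setNames(c(2L, 1L), act[c(9, 10)])),
          productOnly = act[11]),
        g("Synthetica vulgaris A4", "900000004",
          c(core, stats::setNames(3L, act[12]))),
        g("Synthetica rara A5", "900000005",
          c(core, stats::setNames(1L, act[13])),
          productOnly = act[14]),
        g("Synthetica rara A6", "900000006",
          c(core, stats::setNames(c(1L, 1L), act[c(15, 16)]))))
    groupB <- list(
        g("Fictiva insolita B1", "900000011",
          c(core, stats::setNames(c(2L, 1L), act[c(17, 18)]))),
        g("Fictiva insolita B2", "900000012",
          c(core, stats::setNames(1L, act[19])),
          productOnly = act[20]),
        g("Fictiva mirabilis B3", "900000013",
          c(core, stats::setNames(4L, act[21]))),
        g("Fictiva mirabilis B4", "900000014",
          c(core, stats::setNames(1L, act[22])),
          productOnly = act[23]),
        g("Fictiva obscura B5", "900000015",
          c(core, stats::setNames(c(1L, 2L), act[c(24, 25)]))),
        g("Fictiva obscura B6", "900000016",
          c(core, stats::setNames(1L, act[26]))))
    list(labelA = labelA, labelB = labelB, groupA = groupA, groupB = groupB,
         collisionName = "Alcohol dehydrogenase (acceptor)")
}

#' Random small fixture spec for property testing
#'
#' Draws a random microbiome pair: up to `maxGenomes` genomes per group and
#' up to `maxCds` CDSs per genome, with planted ECs (copy numbers 1--3)
#' sampled from the active default entries so that shared and unique ECs
#' arise by chance.
#'
#' @param seed integer seed; fixes the draw.
#' @param maxGenomes,maxCds upper bounds per group / per genome.
#' @return a fixture spec as in [defaultFixtureSpec()].
#' @export
randomFixtureSpec <- function(seed, maxGenomes = 6L, maxCds = 30L) {
    entries <- defaultEnzymeEntries()
    act <- entries$ec[entries$status == "active"]
    withr::with_seed(seed, {
        mk <- function(prefix, gid) {
            n <- sample.int(maxGenomes, 1L)
            lapply(seq_len(n), function(i) {
                nPlant <- sample.int(6L, 1L)
                ecs <- sample(act, nPlant)
                planted <- stats::setNames(sample.int(3L, nPlant,
                                                      replace = TRUE), ecs)
                nPO <- sample(0:2, 1L)
                po <- sample(setdiff(act, ecs), nPO)
                nCds <- max(sum(planted) + nPO + 2L,
                            sample.int(maxCds, 1L))
                list(organism = sprintf("%s organism %d", prefix, i),
                     gi = sprintf("%s%04d", gid, i),
                     planted = planted, productOnly = po,
                     ambiguous = sample(0:1, 1L), nCds = nCds)
            })
        }
        list(labelA = "Microbiome 1", labelB = "Microbiome 2",
             groupA = mk("Alpha", "91"), groupB = mk("Beta", "92"),
             collisionName = "Alcohol dehydrogenase (acceptor)")
    })
}

# expected row-level comparison counts, derived from the planted inventory
# by an independent nested-loop classification over the cross-product of
# rows (never via compareGroups)
.expectedCounts <- function(spec, mode = c("off", "unique", "unique+multi")) {
    mode <- match.arg(mode)
    entries <- defaultEnzymeEntries()
    collisionEcs <- sortEc(entries$ec[vapply(entries$alt, function(a)
        spec$collisionName %in% a, NA)])
    collisionEcs <- head(collisionEcs, 3L)
    rowsOf <- function(group) {
        out <- character()
        for (gspec in group) {
            out <- c(out, rep(names(gspec$planted), gspec$planted))
            if (mode != "off")
                out <- c(out, gspec$productOnly)
            if (mode == "unique+multi" && gspec$ambiguous > 0L)
                out <- c(out, rep(collisionEcs, gspec$ambiguous))
        }
        out
    }
    ra <- rowsOf(spec$groupA)
    rb <- rowsOf(spec$groupB)
    nId <- 0L; nA <- 0L; nB <- 0L
    for (ec in ra) {
        if (any(rb == ec)) nId <- nId + 1L else nA <- nA + 1L
    }
    for (ec in rb) {
        if (any(ra == ec)) nId <- nId + 1L else nB <- nB + 1L
    }
    c(identical = nId, unique_a = nA, unique_b = nB)
}

.writeFixtureGenome <- function(gspec, path, entries, collisionName) {
    nameOf <- function(ec) entries$name[match(ec, entries$ec)]
    cdsList <- list()
    for (ec in names(gspec$planted))
        for (k in seq_len(gspec$planted[[ec]]))
            cdsList[[length(cdsList) + 1L]] <-
                list(product = nameOf(ec), ecs = ec)
    for (ec in gspec$productOnly)
        cdsList[[length(cdsList) + 1L]] <-
            list(product = nameOf(ec), ecs = character())
    if (gspec$ambiguous > 0L)
        for (k in seq_len(gspec$ambiguous))
            cdsList[[length(cdsList) + 1L]] <-
                list(product = collisionName, ecs = character())
    while (length(cdsList) < gspec$nCds)
        cdsList[[length(cdsList) + 1L]] <-
            list(product = "hypothetical protein", ecs = character())
    cdsList <- cdsList[sample.int(length(cdsList))]
    # plasmid-style second LOCUS record for larger genomes
    base <- gsub("[^A-Za-z0-9]", "", gspec$organism)
    base <- toupper(substr(paste0(base, "XXXXXX"), 1L, 8L))
    if (length(cdsList) >= 10L) {
        cut <- floor(length(cdsList) * 0.8)
        lines <- c(.locusText(base, gspec$organism, gspec$gi,
                              cdsList[seq_len(cut)]),
                   .locusText(paste0(base, "P"), gspec$organism, gspec$gi,
                              cdsList[(cut + 1L):length(cdsList)]))
    } else {
        lines <- .locusText(base, gspec$organism, gspec$gi, cdsList)
    }
    writeLines(lines, path)
    path
}

#' Generate a synthetic microbiome pair on disk
#'
#' Writes one GenBank file per genome into `<dir>/groupA` and
#' `<dir>/groupB`, plus the miniature ENZYME flat file the product names
#' were drawn from, and returns the ground-truth expectations implied by the
#' planted inventories. Outputs are byte-identical for a fixed seed.
#'
#' @param dir output directory (created if needed).
#' @param spec fixture spec ([defaultFixtureSpec()], [randomFixtureSpec()]).
#' @param seed integer seed for the CDS shuffling and filler sequence.
#' @return list with `dirA`, `dirB`, `enzymeDat` (paths), `labels`,
#'   `expected` — a list of expected comparison row counts under annotation
#'   mode `off`, `unique` and `unique+multi` — and `spec`.
#' @export
makeMicrobiomePair <- function(dir, spec = defaultFixtureSpec(), seed = 1L) {
    entries <- defaultEnzymeEntries()
    dirA <- file.path(dir, "groupA")
    dirB <- file.path(dir, "groupB")
    dir.create(dirA, recursive = TRUE, showWarnings = FALSE)
    dir.create(dirB, recursive = TRUE, showWarnings = FALSE)
    enzPath <- file.path(dir, "mini_enzyme.dat")
    makeEnzymeDat(enzPath, entries)
    withr::with_seed(seed, {
        for (i in seq_along(spec$groupA))
            .writeFixtureGenome(spec$groupA[[i]],
                                file.path(dirA, sprintf("genome_a%02d.gbk", i)),
                                entries, spec$collisionName)
        for (i in seq_along(spec$groupB))
            .writeFixtureGenome(spec$groupB[[i]],
                                file.path(dirB, sprintf("genome_b%02d.gbk", i)),
                                entries, spec$collisionName)
    })
    list(dirA = dirA, dirB = dirB, enzymeDat = enzPath,
         labels = c(spec$labelA, spec$labelB),
         expected = list(
             off = .expectedCounts(spec, "off"),
             unique = .expectedCounts(spec, "unique"),
             `unique+multi` = .expectedCounts(spec, "unique+multi")),
         spec = spec)
}
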