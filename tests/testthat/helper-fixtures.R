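# Shared fixture builders and independent oracles. Everything here is
# deliberately hand-rolled and simple so it can serve as a reference the
# package code is checked against.

# hand-written mini ENZYME flat file: 3 active (one with alternative names
# and wrapped DE/CA), 1 transferred, 1 deleted
miniEnzymeDatLines <- function() {
    c("ID   4.4.1.1",
      "DE   Cystathionine gamma-lyase.",
      "AN   Gamma-cystathionase.",
      "CA   L-cystathionine + H2O = L-cysteine + NH3 + 2-oxobutanoate.",
      "//",
      "ID   2.1.1.10",
      "DE   Homocysteine",
      "DE   S-methyltransferase.",
      "CA   S-methyl-L-methionine + L-homocysteine =",
      "CA   2 L-methionine.",
      "//",
      "ID   6.3.2.3",
      "DE   Glutathione synthase.",
      "AN   Glutathione synthetase.",
      "AN   GSH synthetase.",
      "CA   ATP + gamma-L-glutamyl-L-cysteine + glycine = ADP + phosphate + glutathione.",
      "//",
      "ID   1.1.1.5",
      "DE   Transferred entry: 1.1.1.303 and 1.1.1.304.",
      "//",
      "ID   1.1.1.74",
      "DE   Deleted entry.",
      "//")
}

# hand-written GenBank record text, independent of the package's generator
toyLocusLines <- function(name, organism, gi, cds, version = TRUE) {
    out <- c(
        sprintf("LOCUS       %-16s %11d bp    DNA     circular BCT 01-JAN-2015",
                name, 90L * max(1L, length(cds))),
        sprintf("DEFINITION  %s test record.", organism),
        sprintf("ACCESSION   %s", name),
        if (version) sprintf("VERSION     %s.1  GI:%s", name, gi),
        sprintf("SOURCE      %s", organism),
        sprintf("  ORGANISM  %s", organism),
        "            Bacteria.",
        "FEATURES             Location/Qualifiers",
        sprintf("     source          1..%d", 90L * max(1L, length(cds))))
    for (i in seq_along(cds)) {
        out <- c(out, sprintf("     CDS             %d..%d",
                              (i - 1L) * 90L + 1L, i * 90L))
        if (!is.null(cds[[i]]$product))
            out <- c(out, sprintf("                     /product=\"%s\"",
                                  cds[[i]]$product))
        for (ec in cds[[i]]$ecs)
            out <- c(out, sprintf("                     /EC_number=\"%s\"",
                                  ec))
    }
    c(out,
      "ORIGIN",
      "        1 acgtacgtac gtacgtacgt",
      "//")
}

writeToyGenBank <- function(path, lociList) {
    writeLines(unlist(lapply(lociList, function(l)
        toyLocusLines(l$name, l$organism, l$gi, l$cds,
                      version = isTRUE(l$version) || is.null(l$version)))),
        path)
    path
}

# independent brute-force classifier: walks the cross-product of rows
bruteCompareCounts <- function(ecsA, ecsB) {
    nId <- 0L; nA <- 0L; nB <- 0L
    for (ec in ecsA) {
        hit <- FALSE
        for (other in ecsB) if (identical(ec, other)) { hit <- TRUE; break }
        if (hit) nId <- nId + 1L else nA <- nA + 1L
    }
    for (ec in ecsB) {
        hit <- FALSE
        for (other in ecsA) if (identical(ec, other)) { hit <- TRUE; break }
        if (hit) nId <- nId + 1L else nB <- nB + 1L
    }
    c(identical = nId, unique_a = nA, unique_b = nB)
}

# in-memory genome holding one CDS per planted EC copy (no annotation step)
genomeFromPlanted <- function(gspec) {
    ecs <- rep(names(gspec$planted), gspec$planted)
    GenomeRecord(gspec$gi, gspec$organism,
                 product = rep(NA_character_, length(ecs)),
                 ecNumbers = as.list(ecs))
}

# hand-enumerated mini index for the three-outcome annotation rule
handEntries <- function() {
    data.frame(
        ec = c("1.1.1.1", "2.2.2.2", "3.3.3.3", "1.1.1.2", "2.3.4.5",
               "6.1.1.1"),
        name = c("alpha enzyme", "beta ortholog", "beta paralog",
                 "delta enzyme", "epsilon enzyme", "zeta enzyme"),
        alt = I(list(character(), "beta enzyme", "beta enzyme",
                     "gamma enzyme", "gamma enzyme", "gamma enzyme")),
        activity = rep("A = B", 6),
        status = rep("active", 6),
        targets = I(rep(list(character()), 6)),
        stringsAsFactors = FALSE)
}

handDb <- function() {
    entries <- handEntries()
    # give 1.1.1.1 the 4-way shared name too
    entries$alt[[1]] <- "gamma enzyme"
    path <- withr::local_tempfile(fileext = ".dat",
                                  .local_envir = parent.frame())
    readEnzymeDb(makeEnzymeDat(path, entries)$path)
}
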