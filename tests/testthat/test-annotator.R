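test_that("the three-outcome rule holds exhaustively over a hand-enumerated index", {
    db <- handDb()
    idx <- nameIndex(db)
    # every key of the index must classify by its own EC count
    for (key in names(idx)) {
        m <- matchProduct(key, db)
        k <- length(idx[[key]])
        if (k == 1L) {
            expect_equal(m$outcome, "unique")
            expect_equal(m$assigned_ecs, idx[[key]])
            expect_equal(m$reliability, 1L)
        } else {
            expect_equal(m$outcome, "multiple")
            expect_equal(m$assigned_ecs, head(idx[[key]], 3L))
            expect_equal(m$reliability, 0L)
            expect_gte(length(m$assigned_ecs), 2L)
            expect_lte(length(m$assigned_ecs), 3L)
        }
        expect_equal(m$match_stage, "exact")
    }
    none <- matchProduct("hypothetical protein", db)
    expect_equal(none$outcome, "none")
    expect_length(none$assigned_ecs, 0L)
    expect_equal(none$reliability, 1L)
})

test_that("a 4-way shared name assigns the first three ECs in ascending order", {
    m <- matchProduct("Gamma Enzyme", handDb())
    expect_equal(m$outcome, "multiple")
    expect_equal(m$assigned_ecs, c("1.1.1.1", "1.1.1.2", "2.3.4.5"))
    expect_equal(m$reliability, 0L)
})

test_that("known product names match uniquely against the curated entries", {
    db <- readEnzymeDb(makeEnzymeDat(withr::local_tempfile())$path)
    m <- matchProduct("Cystathionine beta-synthase", db)
    expect_equal(m$outcome, "unique")
    expect_equal(m$assigned_ecs, "4.2.1.22")
    expect_equal(m$reliability, 1L)
    expect_equal(matchProduct("hypothetical protein", db)$outcome, "none")
})

test_that("the substring fallback only runs when enabled and is recorded", {
    db <- handDb()
    exact <- matchProduct("alpha enzyme precursor", db)
    expect_equal(exact$outcome, "none")
    sub <- matchProduct("alpha enzyme precursor", db, substring = TRUE)
    expect_equal(sub$outcome, "unique")
    expect_equal(sub$assigned_ecs, "1.1.1.1")
    expect_equal(sub$match_stage, "substring")
})

test_that("annotation touches only unannotated CDSs and tallies correctly", {
    db <- handDb()
    rec <- GenomeRecord("9", "Toya decem",
        product = c("alpha enzyme", "beta enzyme", "delta enzyme",
                    "zeta enzyme", "hypothetical protein", "unknown",
                    "pre-annotated", "alpha enzyme", NA, "mystery"),
        ecNumbers = c(rep(list(character()), 6), list("5.5.5.5"),
                      list("1.1.1.1"), rep(list(character()), 2)))
    out <- annotateGenome(rec, db)
    s <- out$summary
    expect_equal(s$total_cds, 10L)
    expect_equal(s$already_annotated, 2L)
    expect_equal(s$newly_annotated, 4L)   # alpha, beta(multi), delta, zeta
    expect_equal(s$multi_flagged, 1L)
    expect_equal(s$untouched, 4L)
    expect_equal(s$already_annotated + s$newly_annotated + s$untouched,
                 s$total_cds)
    cds <- cdsTable(out$record)
    expect_equal(cds$ec_numbers[[7]], "5.5.5.5")   # originals never altered
    expect_equal(cds$origin[7], "original")
    expect_equal(cds$ec_numbers[[2]], c("2.2.2.2", "3.3.3.3"))
    expect_equal(cds$reliability[2], 0L)
})

test_that("annotation is idempotent and a fully annotated record is a fixed point", {
    db <- handDb()
    rec <- GenomeRecord("10", "Toya iterata",
                        product = c("alpha enzyme", "beta enzyme", "noise"),
                        ecNumbers = rep(list(character()), 3))
    once <- annotateGenome(rec, db)
    twice <- annotateGenome(once$record, db)
    expect_equal(twice$record, once$record)
    expect_equal(twice$summary$newly_annotated, 0L)
    expect_equal(twice$summary$already_annotated, 2L)
    pre <- annotateGenome(once$record, db)$record
    expect_equal(pre, once$record)
})

test_that("unique-only mode leaves multi-matches unannotated; off does nothing", {
    db <- handDb()
    rec <- GenomeRecord("11", "Toya modalis",
                        product = c("alpha enzyme", "beta enzyme"),
                        ecNumbers = rep(list(character()), 2))
    uo <- annotateGenome(rec, db, mode = "unique-only")
    expect_equal(cdsTable(uo$record)$ec_numbers[[2]], character())
    expect_equal(uo$summary$newly_annotated, 1L)
    expect_equal(uo$summary$multi_flagged, 1L)   # tallied even if unwritten
    off <- annotateGenome(rec, db, mode = "off")
    expect_equal(off$record, rec)
    expect_equal(off$summary$newly_annotated, 0L)
})

test_that("unique assignments are sound against the raw records, bypassing the index", {
    db <- readEnzymeDb(makeEnzymeDat(withr::local_tempfile())$path)
    rec <- enzymeRecords(db)
    act <- rec[rec$status == "active", ]
    dir <- withr::local_tempdir()
    fx <- makeMicrobiomePair(dir, randomFixtureSpec(29L), seed = 29L)
    for (f in list.files(c(fx$dirA, fx$dirB), full.names = TRUE)) {
        g <- readGenBank(f)
        ann <- annotateGenome(g, db)$record
        cds <- cdsTable(ann)
        denovo <- which(cds$origin == "de_novo" & cds$reliability == 1L)
        for (i in denovo) {
            ec <- cds$ec_numbers[[i]]
            j <- match(ec, act$ec_number)
            names_j <- normalizeEnzymeName(c(act$recommended_name[j],
                                             act$alt_names[[j]]))
            expect_true(normalizeEnzymeName(cds$product[i]) %in% names_j,
                        label = paste("soundness of", cds$product[i]))
        }
    }
})

test_that("enlarging the index never decreases newly_annotated", {
    entries <- defaultEnzymeEntries()
    small <- readEnzymeDb(makeEnzymeDat(withr::local_tempfile(),
                                        entries[1:10, ])$path)
    full <- readEnzymeDb(makeEnzymeDat(withr::local_tempfile(),
                                       entries)$path)
    nm <- entries$name[entries$status == "active"]
    rec <- GenomeRecord("12", "Toya monotona",
                        product = c(nm[c(2, 5, 12, 20, 25)], "junk"),
                        ecNumbers = rep(list(character()), 6))
    nSmall <- annotateGenome(rec, small)$summary$newly_annotated
    nFull <- annotateGenome(rec, full)$summary$newly_annotated
    expect_gte(nFull, nSmall)
})
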