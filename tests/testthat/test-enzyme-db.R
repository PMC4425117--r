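test_that("an empty stream parses to zero records", {
    rec <- parseEnzymeDat(character())
    expect_equal(nrow(rec), 0L)
    expect_true(all(c("ec_number", "status", "alt_names") %in% names(rec)))
})

test_that("a cystathionine gamma-lyase block parses with period stripped", {
    rec <- parseEnzymeDat(c(
        "ID   4.4.1.1",
        "DE   Cystathionine gamma-lyase.",
        "CA   L-cystathionine + H2O = L-cysteine + NH3 + 2-oxobutanoate.",
        "//"))
    expect_equal(nrow(rec), 1L)
    expect_equal(rec$status, "active")
    expect_equal(rec$recommended_name, "Cystathionine gamma-lyase")
    expect_equal(rec$catalytic_activity,
                 "L-cystathionine + H2O = L-cysteine + NH3 + 2-oxobutanoate")
})

test_that("the hand-written mini file yields 5 records, exactly 3 active", {
    rec <- parseEnzymeDat(miniEnzymeDatLines())
    expect_equal(nrow(rec), 5L)
    expect_equal(sum(rec$status == "active"), 3L)
    tr <- rec[rec$status == "transferred", ]
    expect_equal(tr$ec_number, "1.1.1.5")
    expect_equal(tr$transfer_targets[[1]], c("1.1.1.303", "1.1.1.304"))
    expect_equal(rec$ec_number[rec$status == "deleted"], "1.1.1.74")
})

test_that("multi-line DE and CA fields concatenate with single spaces", {
    rec <- parseEnzymeDat(miniEnzymeDatLines())
    hc <- rec[rec$ec_number == "2.1.1.10", ]
    expect_equal(hc$recommended_name, "Homocysteine S-methyltransferase")
    expect_equal(hc$catalytic_activity,
                 "S-methyl-L-methionine + L-homocysteine = 2 L-methionine")
})

test_that("a malformed ID line is reported with its line number and skipped", {
    lines <- c("ID   not-an-ec", "DE   Bogus.", "//", miniEnzymeDatLines())
    expect_warning(rec <- parseEnzymeDat(lines), "line 1")
    expect_equal(nrow(rec), 5L)
})

test_that("a truncated final record is dropped with a warning", {
    lines <- c(miniEnzymeDatLines(), "ID   9.9.9.9", "DE   Dangling.")
    expect_warning(rec <- parseEnzymeDat(lines), "truncated")
    expect_equal(nrow(rec), 5L)
    expect_false("9.9.9.9" %in% rec$ec_number)
})

test_that("serialize/parse round-trips records field-identically", {
    records <- enzymeRecords(EnzymeDb(parseEnzymeDat(miniEnzymeDatLines())))
    again <- parseEnzymeDat(writeEnzymeDat(records))
    expect_equal(again, records)
    # and on the full curated fixture set
    full <- makeEnzymeDat(withr::local_tempfile(fileext = ".dat"))
    expect_equal(parseEnzymeDat(full$path), full$records)
})

test_that("name normalization is idempotent and strips the right things", {
    raw <- c("Cystathionine  gamma-lyase.", "\"Arginase.\"",
             " Glutathione synthase ", "TRAILING..", "plain")
    norm <- normalizeEnzymeName(raw)
    expect_equal(norm[1], "cystathionine gamma-lyase")
    expect_equal(norm[2], "arginase")
    expect_equal(norm[3], "glutathione synthase")
    expect_equal(normalizeEnzymeName(norm), norm)
})

test_that("a shared alternative name maps to all its ECs in ascending order", {
    rec <- parseEnzymeDat(c(
        "ID   1.1.1.2",
        "DE   Alcohol dehydrogenase (NADP(+)).",
        "AN   Alcohol dehydrogenase (acceptor).",
        "//",
        "ID   1.1.1.1",
        "DE   Alcohol dehydrogenase.",
        "AN   Alcohol dehydrogenase (acceptor).",
        "//"))
    idx <- buildNameIndex(rec)
    expect_equal(idx[["alcohol dehydrogenase (acceptor)"]],
                 c("1.1.1.1", "1.1.1.2"))
})

test_that("zero records build an empty index; a known name maps to its EC", {
    expect_length(buildNameIndex(parseEnzymeDat(character())), 0L)
    idx <- buildNameIndex(parseEnzymeDat(miniEnzymeDatLines()))
    expect_equal(idx[["homocysteine s-methyltransferase"]], "2.1.1.10")
})

test_that("every active record is reachable from each of its names; no inactive EC leaks", {
    db <- EnzymeDb(parseEnzymeDat(writeEnzymeDat(
        makeEnzymeDat(withr::local_tempfile())$records)))
    rec <- enzymeRecords(db)
    idx <- nameIndex(db)
    act <- rec[rec$status == "active", ]
    for (i in seq_len(nrow(act))) {
        for (nm in c(act$recommended_name[i], act$alt_names[[i]]))
            expect_true(act$ec_number[i] %in%
                            idx[[normalizeEnzymeName(nm)]],
                        label = paste("lookup of", nm))
    }
    inactive <- rec$ec_number[rec$status != "active"]
    expect_length(intersect(unlist(idx), inactive), 0L)
})

test_that("lookupEc fills report columns, reports transfers, and signals misses", {
    db <- readEnzymeDb(makeEnzymeDat(withr::local_tempfile())$path)
    gs <- lookupEc(db, "6.3.2.3")
    expect_true(gs$found)
    expect_equal(gs$recommended_name, "Glutathione synthase")
    expect_equal(gs$catalytic_activity,
                 "ATP + gamma-l-glutamyl-l-cysteine + glycine = ADP + phosphate + glutathione")
    tr <- lookupEc(db, "1.1.1.5")
    expect_equal(tr$status, "transferred")
    expect_equal(tr$transfer_targets, c("1.1.1.303", "1.1.1.304"))
    miss <- lookupEc(db, "9.9.9.9")
    expect_false(miss$found)
    expect_equal(miss$status, "not_found")
    expect_error(lookupEc(db, "bogus"), "valid EC")
})

test_that("partial EC identifiers parse, are flagged, and stay literal", {
    rec <- parseEnzymeDat(c("ID   1.2.3.-", "DE   Partial enzyme.", "//"))
    expect_true(rec$partial)
    idx <- buildNameIndex(rec)
    expect_equal(idx[["partial enzyme"]], "1.2.3.-")
})
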