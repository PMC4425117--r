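test_that("a simple record reads with products, ECs, GI and organism", {
    f <- writeToyGenBank(withr::local_tempfile(fileext = ".gbk"), list(
        list(name = "TOY1", organism = "Toya minima", gi = "12345", cds = list(
            list(product = "alcohol dehydrogenase", ecs = "1.1.1.1"),
            list(product = "hypothetical protein", ecs = character()),
            list(product = NULL, ecs = character())))))
    rec <- readGenBank(f)
    expect_equal(totalCds(rec), 3L)
    expect_equal(giAccession(rec), "12345")
    expect_equal(organismName(rec), "Toya minima")
    cds <- cdsTable(rec)
    expect_equal(cds$ec_numbers[[1]], "1.1.1.1")
    expect_equal(cds$origin, rep("original", 3))
    expect_equal(cds$reliability, rep(1L, 3))
    expect_true(is.na(cds$product[3]))
})

test_that("multiple LOCUS records in one file concatenate their CDSs", {
    f <- writeToyGenBank(withr::local_tempfile(fileext = ".gbk"), list(
        list(name = "CHR1", organism = "Toya plasmidifera", gi = "777",
             cds = list(list(product = "p1", ecs = "1.1.1.1"),
                        list(product = "p2", ecs = character()))),
        list(name = "PLAS1", organism = "Toya plasmidifera", gi = "777",
             version = FALSE,
             cds = list(list(product = "p3", ecs = character()),
                        list(product = "p4", ecs = "2.2.2.2"),
                        list(product = "p5", ecs = character())))))
    rec <- readGenBank(f)
    expect_equal(totalCds(rec), 5L)
    expect_equal(giAccession(rec), "777")
})

test_that("a record with no CDS features reads with a warning", {
    f <- writeToyGenBank(withr::local_tempfile(fileext = ".gbk"), list(
        list(name = "EMPTY", organism = "Toya vacua", gi = "1", cds = list())))
    expect_warning(rec <- readGenBank(f), "no CDS")
    expect_equal(totalCds(rec), 0L)
    expect_equal(nrow(extractEnzymeRows(rec)), 0L)
})

test_that("enzyme rows enumerate (CDS, EC) pairs with gene copies kept", {
    rec <- GenomeRecord("42", "Copycat organism",
                        product = c("a", "a", "b", "c"),
                        ecNumbers = list("1.2.7.3", "1.2.7.3",
                                         c("4.4.1.1", "6.3.2.3"),
                                         character()))
    rows <- extractEnzymeRows(rec)
    expect_equal(nrow(rows), 4L)
    expect_equal(sum(rows$ec_number == "1.2.7.3"), 2L)
    expect_equal(nrow(rows), sum(lengths(cdsTable(rec)$ec_numbers)))
    # five copies of the same EC yield five rows
    five <- GenomeRecord("43", "Multicopy organism",
                         product = rep("2-oxoglutarate synthase", 5),
                         ecNumbers = rep(list("1.2.7.3"), 5))
    expect_equal(nrow(extractEnzymeRows(five)), 5L)
})

test_that("writing with no de novo annotations is byte-identical", {
    f <- writeToyGenBank(withr::local_tempfile(fileext = ".gbk"), list(
        list(name = "TOY2", organism = "Toya intacta", gi = "555", cds = list(
            list(product = "arginase", ecs = "3.5.3.1"),
            list(product = "hypothetical protein", ecs = character())))))
    out <- withr::local_tempfile(fileext = ".gbk")
    writeGenBankAnnotations(readGenBank(f), f, out)
    expect_identical(readLines(out), readLines(f))
})

test_that("a multi-match CDS is written with exactly 3 EC qualifiers and a designation", {
    db <- handDb()   # "gamma enzyme" is shared by 4 ECs
    f <- writeToyGenBank(withr::local_tempfile(fileext = ".gbk"), list(
        list(name = "TOY3", organism = "Toya ambigua", gi = "556", cds = list(
            list(product = "gamma enzyme", ecs = character())))))
    ann <- annotateGenome(readGenBank(f), db)$record
    out <- withr::local_tempfile(fileext = ".gbk")
    writeGenBankAnnotations(ann, f, out)
    lines <- readLines(out)
    expect_equal(sum(grepl("/EC_number=", lines)), 3L)
    expect_equal(sum(grepl("multi-EC designation", lines)), 1L)
    back <- readGenBank(out)
    expect_equal(cdsTable(back)$reliability, 0L)
    expect_equal(cdsTable(back)$origin, "de_novo")
    expect_equal(cdsTable(back)$ec_numbers[[1]],
                 c("1.1.1.1", "1.1.1.2", "2.3.4.5"))
})

test_that("read-write-read round-trips and conserves features on all fixtures", {
    dir <- withr::local_tempdir()
    fx <- makeMicrobiomePair(dir, defaultFixtureSpec(), seed = 11L)
    db <- readEnzymeDb(fx$enzymeDat)
    files <- list.files(c(fx$dirA, fx$dirB), full.names = TRUE)
    expect_gt(length(files), 0L)
    for (f in files) {
        rec <- readGenBank(f)
        out <- tempfile(fileext = ".gbk")
        writeGenBankAnnotations(rec, f, out)
        again <- readGenBank(out)
        again@sourcePath <- rec@sourcePath
        expect_equal(again, rec, label = paste("roundtrip", basename(f)))

        ann <- annotateGenome(rec, db)$record
        out2 <- tempfile(fileext = ".gbk")
        writeGenBankAnnotations(ann, f, out2)
        back <- readGenBank(out2)
        back@sourcePath <- ann@sourcePath
        expect_equal(back, ann,
                     label = paste("annotated roundtrip", basename(f)))
        # conservation: CDS count and product text never change
        expect_equal(totalCds(back), totalCds(rec))
        expect_equal(cdsTable(back)$product, cdsTable(rec)$product)
        unlink(c(out, out2))
    }
})

test_that("the reader agrees with an independent GenBank parser", {
    dir <- withr::local_tempdir()
    fx <- makeMicrobiomePair(dir, defaultFixtureSpec(), seed = 3L)
    f <- list.files(fx$dirA, full.names = TRUE)[1]
    rec <- readGenBank(f)
    script <- withr::local_tempfile(fileext = ".py", lines = c(
        "import sys, json",
        "from Bio import SeqIO",
        "recs = list(SeqIO.parse(sys.argv[1], 'genbank'))",
        "cds = [ft for r in recs for ft in r.features if ft.type == 'CDS']",
        "out = {",
        "  'n_cds': len(cds),",
        "  'organism': recs[0].annotations['organism'],",
        "  'ecs': sorted(q for ft in cds",
        "                for q in ft.qualifiers.get('EC_number', [])),",
        "  'products': sorted(q for ft in cds",
        "                     for q in ft.qualifiers.get('product', [])),",
        "}",
        "print(json.dumps(out))"))
    json <- system2("python", c(script, f), stdout = TRUE)
    oracle <- jsonlite::fromJSON(paste(json, collapse = ""))
    expect_equal(totalCds(rec), oracle$n_cds)
    expect_equal(organismName(rec), oracle$organism)
    expect_equal(sort(unlist(cdsTable(rec)$ec_numbers)),
                 sort(oracle$ecs), ignore_attr = TRUE)
    prods <- cdsTable(rec)$product
    expect_equal(sort(prods[!is.na(prods)]), sort(oracle$products),
                 ignore_attr = TRUE)
})
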