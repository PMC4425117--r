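# enzymome

Comparative enzyme profiling of artificial metagenomes built from GenBank
genome records.

## What problem this solves

A common question in microbiome research is: *which enzymatic capabilities
distinguish one microbial community from another?* When the communities of
interest are well characterized at the species level — for example a
"control" gut community versus one associated with a disease state — a full
shotgun-metagenomics pipeline is unnecessary. Instead, an **artificial
metagenome** can be assembled from the curated single-organism genome
records of the community's members, and the comparison reduced to the
enzymes those genomes encode.

`enzymome` implements this approach for R users working with standard
public resources:

* **GenBank flat files** provide each organism's coding sequences (CDS)
  with `/product` names and, where present, `/EC_number` annotations.
* The **ENZYME flat file** (ExPASy `enzyme.dat` dialect) provides the
  Enzyme Commission nomenclature: recommended and alternative names and the
  catalyzed reaction for each EC number.

Enzyme identity is judged **by EC number only**. Two organisms may encode
the same activity under slightly different protein names or sequences; the
standardized EC identifier is what lets an automated comparison match
identical enzymes correctly.

## The method

1. **Parse** the ENZYME flat file into records and build a name index over
   all *active* entries (transferred/deleted entries are excluded).
2. **Read** each genome's GenBank file; all LOCUS records in a file
   (chromosome + plasmids) merge into one genome.
3. **Annotate de novo**: each CDS lacking an EC number has its product name
   normalized and looked up. The lookup has three possible outcomes —
   *no match*, *one unique match*, or *more than one match*. Unique matches
   are written with reliability 1; multi-matches get their first three
   candidate ECs (ascending order) and **reliability 0**, flagging them for
   manual curation. Pre-existing annotations are never altered.
4. **Compare** two labelled groups at the level of enzyme *rows* — one row
   per (CDS, EC) pair, so **gene copies are counted, not collapsed** — into
   three sections: ECs present in both groups (*identical*), only in group
   A, or only in group B. Multi-copy genes display as `organism (×n)`.
5. **Coverage statistics** per genome: total CDSs, CDSs with ≥ 1 EC before
   and after annotation, multi-match designations, the reliable ("actual")
   EC total, and percent coverage/increase.

## Worked example

The package ships a fixture generator that writes a pair of synthetic
microbiome groups (GenBank files with planted enzyme inventories) plus a
miniature ENZYME flat file, so the whole pipeline runs offline:

```r
library(enzymome)

fx  <- makeMicrobiomePair("demo", defaultFixtureSpec(), seed = 1)
cfg <- newRunConfig(fx$dirA, fx$dirB,
                    labelA = "control", labelB = "autism",
                    enzymeDat = fx$enzymeDat, outPrefix = "demo/run")
res <- runCompare(cfg)
res$result
#> ComparisonResult: control vs autism
#>   identical: 72 | unique to control: 20 | unique to autism: 15 (rows; gene copies included)
```

72 enzyme rows carry ECs found in both groups; 20 rows are unique to the
control group and 15 to the autism group. Because the counting unit is the
(CDS, EC) row, a gene present in five copies contributes five rows — the
display layer collapses them:

```r
rows <- comparisonRows(res$result)
groupWithMultiplicity(rows[rows$section == "unique_a", ])[1:3, c("ec_number", "display")]
#>   ec_number                     display
#> 1  1.11.1.1 Synthetica vulgaris A4 (×3)
#> 2  1.11.1.9          Synthetica rara A5
#> 3  1.15.1.2          Synthetica rara A5
```

Per-genome coverage before/after de novo annotation:

```r
head(formatCoverage(res$coverage), 3)
#>               organism total_cds ec_cds_original pct_original ec_cds_updated multi_flagged actual_ec pct_updated pct_increase
#> 1  Fictiva insolita B1        60               7        11.67              8             1         7       11.67         0.00
#> 2  Fictiva insolita B2        60               5         8.33              7             1         6       10.00        20.00
#> 3 Fictiva mirabilis B3        60               8        13.33              9             1         8       13.33         0.00
```

`runCompare()` also writes three TSVs (`run.report.tsv` with the
three-section row-level report, `run.summary.tsv` with the category counts,
`run.coverage.tsv`) — byte-identical for the same inputs and configuration.

A command-line interface with subcommands `compare`, `annotate`, `stats`
and `fixtures` lives at `inst/scripts/enzymome.R`:

```sh
Rscript inst/scripts/enzymome.R compare \
    --group-a demo/groupA --group-b demo/groupB \
    --label-a control --label-b autism \
    --enzyme-dat demo/mini_enzyme.dat --out-prefix demo/run
```

## Scope

The package compares enzyme complements; it does not reconstruct metabolic
networks, score pathway completeness, or perform sequence-similarity
(BLAST-style) annotation. A network fetch helper (`fetchGenBank()`) is
provided for convenience but nothing in the analysis or test path requires
network access.
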