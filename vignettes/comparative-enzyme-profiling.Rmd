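---
title: "Comparative enzyme profiling of artificial metagenomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative enzyme profiling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enzymome)
```

## The model

`enzymome` compares the enzyme complements of two microbial communities
modelled as *artificial metagenomes*: each community is a set of curated
single-organism GenBank genome records rather than environmental sequencing
reads. The unit of enzyme identity is the Enzyme Commission (EC) number — a
four-field dotted identifier classifying the catalyzed reaction — because
protein names and sequences vary across organisms while the EC identifier
does not. The method is text mining over annotations: no sequence content is
ever interpreted.

The pipeline has four stages, each exposed as its own function:

1. `readEnzymeDb()` parses the ENZYME nomenclature flat file and builds a
   name index over active entries.
2. `readGenBank()` flattens one GenBank file (all LOCUS records: chromosome
   plus plasmids) into a `GenomeRecord` of CDS features with `/product`
   names and `/EC_number` annotations.
3. `annotateGenome()` assigns ECs de novo to un-annotated CDSs by product
   name lookup.
4. `compareGroups()` classifies every enzyme row of two labelled groups as
   identical / unique-A / unique-B; `coverageStats()` tallies per-genome
   annotation coverage.

### The counting unit

Throughout the comparison, the unit is the **(CDS, EC) row**. A CDS
annotated with two ECs contributes two rows; two CDSs carrying the same EC
(gene copies) contribute two rows. Category counts therefore deliberately
include gene copies — they measure annotation mass, not distinct enzyme
sets — and the display layer (`groupWithMultiplicity()`) collapses copies
into an `organism (×n)` notation instead. For coverage statistics the unit
is the **CDS bearing at least one EC annotation**, not the qualifier count:
only that unit keeps "actual EC total = total − multi-match designations"
internally consistent.

### The three-outcome annotation rule

A product-name lookup has exactly three outcomes:

* **none** — the CDS stays untouched;
* **unique** — the single matching EC is assigned with reliability 1;
* **multiple** — the first three candidate ECs are assigned with
  **reliability 0** and a machine-readable low-reliability designation is
  placed in the output file, marking the CDS for manual curation.

Reliability is binary by design: 1 for original annotations and unique de
novo matches, 0 for ambiguous multi-matches. Reliability-0 rows participate
fully in the comparison and carry their flag into the report as a column,
not a filter — downstream users decide whether to trust them.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `annotateMode` | `"unique+multi"` | whether de novo annotation writes unique matches only, unique and multi-matches, or nothing (`"off"`). Both restricted modes exist because a comparison can meaningfully be run on original annotations only. |
| `substring` / `substringFallback` | `FALSE` | after an exact miss, accept index keys containing the product name (or contained in it). Off by default: exact matching is conservative and reproducible; product strings with strain suffixes are the reason the fallback exists. The match stage is recorded per assignment. |
| `sentinel` | `"unresolved"` | report text for ECs the nomenclature cannot resolve; a missing EC never aborts a run. |
| labels | "Microbiome 1"/"Microbiome 2" | group labels; must differ, echoed into report headers. |

Alternative names (`AN` lines) are indexed alongside recommended names by
default. This widens recall at the cost of more multi-matches; because the
index is built once from the record table, restricting to recommended names
is a one-line filter on `enzymeRecords()` before `EnzymeDb()` if a stricter
index is wanted.

## Name normalization

ENZYME names end in a period; GenBank `/product` values do not. The
normalization applied to both sides is: trim, strip surrounding quotes,
collapse whitespace runs, strip trailing period(s), lowercase. Trailing
periods are stripped greedily (not just one) so that normalization is
idempotent — index keys are stable under re-normalization.

## Deterministic choices

* **Multi-match order**: candidates are reported in ascending EC order
  (numeric by field; a trailing `-` sorts last). The cap of three recorded
  candidates follows the convention of printing the first three matches
  into the annotated file.
* **Ties/duplicates**: the same EC reachable via a recommended and an
  alternative name counts once.
* **Transferred and deleted entries** are parsed, retained for lookup and
  reporting, but never enter the name index and are not followed to their
  transfer targets. Silent redirection would inflate matches with
  annotations the source data do not support.
* **Partial EC identifiers** (`n.n.n.-`) are parsed, indexed and flagged;
  in comparisons they are literal strings. Prefix semantics would silently
  merge enzyme classes.
* **Row order** in results and reports: section, then EC (numeric field
  order), organism, GI — so identical inputs give byte-identical reports.
* **Display rounding** of coverage percentages is round-half-even to two
  decimals (base R `round`). This was chosen after checking the reference
  coverage table the package reproduces: its single exact tie
  (100 × 27/480 = 5.625, printed 5.62) rounds to even, while every other
  printed cell is insensitive to the rule. Full precision is always kept
  internally; rounding is display-only.
* **Undefined percentages** are blank (`NA`), never 0 or infinite: percent
  increase when the original file had no EC annotations, all percentages
  when a genome has no CDSs.

## Degenerate inputs

Empty ENZYME streams parse to zero records; malformed `ID` lines are
warned about with their line number and skipped; a truncated final record
is dropped with a warning. GenBank files without CDS features yield a valid
zero-CDS genome and a warning. In multi-file runs, unreadable files abort
by default or are skipped with a warning under `skipBadFiles = TRUE`.
Identical group labels and empty groups are rejected before any I/O.

## The fixture generator

`makeMicrobiomePair()` writes a pair of genome groups whose planted enzyme
inventories *fully determine* the expected comparison counts, which are
returned alongside the files and computed independently (a nested-loop
classification over the planted rows, not a call into the comparator). The
generator emulates:

* multi-record files (chromosome + plasmid-style LOCUS records),
* pre-annotated CDSs (`/product` + `/EC_number`), matchable product-only
  CDSs, ambiguous CDSs carrying a planted collision name shared by two EC
  entries, and "hypothetical protein" filler,
* gene copies (×2–×5) and a shared enzyme core between the groups.

The default spec mirrors the study conditions at reduced scale: two groups
of six genomes (a reduced control-vs-autism comparison), 60 CDSs per
genome, and original EC coverage inside the 12–25% band regarded as good
coverage for annotated bacterial genomes. Property tests use randomized
specs of up to 6 genomes × 30 CDSs; the comparator-vs-oracle check runs
200 such pairs and the end-to-end check five specs under three annotation
modes — small enough to run in seconds, large enough to hit collisions,
copies and empty sections by chance.

What the generator does **not** emulate — and hence what green tests do not
demonstrate about real data: realistic community composition or abundances,
the messiness of real product strings (typos, strain suffixes, gene symbols
embedded in names), wrapped multi-line qualifiers in the wild variety real
GenBank files show, release-to-release drift of the ENZYME name sets (which
changes multi-match outcomes), and the sheer annotation sparsity of poorly
covered genomes. The bundled nomenclature fixture (~36 entries) is a
miniature; a real analysis should use a full ENZYME release.

## Storage and interfaces

Results are relational tables (data.frames) persisted as keyed TSV files —
the row-level three-section report, a counts summary, and the coverage
table — rather than a database server; the tables are queryable with
ordinary subsetting and the TSVs round-trip through `parseReport()`. The
command-line interface (`inst/scripts/enzymome.R`) is a thin wrapper over
`runCompare()` and friends with subcommands `compare`, `annotate`, `stats`
and `fixtures`.

## Known limitations

* Annotation recall is bounded by product-name hygiene: exact matching
  misses paraphrased names, and the substring fallback trades precision for
  recall without scoring candidates.
* EC-level identity ignores substrate specificity differences within an EC
  and cannot see enzymes that were never annotated or named recognizably;
  sequence-similarity annotation is explicitly out of scope.
* Multi-match resolution is deferred to manual curation; the package only
  flags and caps candidates.
* Coverage percentages measure annotation coverage, not annotation
  correctness.
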