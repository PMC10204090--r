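---
title: "Mining transcription-factor biosensors from catabolic gene neighborhoods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining transcription-factor biosensors from catabolic gene neighborhoods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfbscout)
library(dplyr)
```

## The model

Bacteria that catabolise a small molecule usually cluster the genes for the
consecutive degradation steps into an operon, and very often a
transcriptional regulator responsive to that molecule sits immediately
upstream, transcribed divergently from a shared intergenic region. LysR-type
regulators in particular follow this architecture. tfbscout exploits it in
reverse: given a metabolite, find genomes in which an enzymatic degradation
chain is encoded as a compact co-oriented gene cluster, then look for the
divergently oriented regulator. Each regulator–operon pair is a candidate
transcription-factor-based biosensor (TFB) for the metabolite, ranked by how
cleanly it fits the divergent-promoter picture.

The procedure has four stages.

**1. Chain enumeration.** From a knowledge base of directed reactions
(substrates, products, EC numbers), every reaction consuming the seed
compound is expanded depth-first, branching once per product and once per
full EC number, until `max_len` steps; all chains with between `min_len` and
`max_len` steps are kept. Traversal honours the *written* direction of each
equation: a compound that the knowledge base only ever writes on the product
side is never a chain start and never continued through. This directionality
is deliberate — it is what makes the search blind to compounds recorded only
as products (the mirror-image enantiomer of a racemase substrate, for
example) — and `treat_reversible = TRUE` relaxes it for knowledge bases
where direction is not meaningful. A chain never revisits a compound on its
own consumed path, which cuts trivial cycles; continuations through shared
cofactors are *not* filtered by default (an explicit
`exclude_compounds` currency list is available) because deciding what counts
as a currency metabolite is compound-specific and better done as visible
post-hoc triage than silently inside the enumerator. Chains are deduplicated
by their ordered EC sequence; reactions, ECs and products are expanded in
lexicographic order so the kept representative and the output order are
reproducible. A reaction carrying several full EC numbers branches once per
EC: a chain's identity is its EC sequence, so each annotation must be
independently reachable. Partial EC numbers (`1.1.1.-`) are excluded from
chain steps by default since they cannot be linked to genes reliably.

**2. Genome screening.** For each chain, the organisms encoding *every* step
(set intersection over the per-EC organism lists) are screened. Genomes are
NCBI-assembly-style feature tables: CDS rows only, 1-based inclusive
coordinates, sorted by start and given a dense per-replicon gene index. The
chain's candidate genes are matched to locus tags case-insensitively; when a
step has several genomic copies, copy combinations are enumerated tightest
genomic span first, capped at 50 per organism and chain to avoid paralog
blow-up.

**3. Operon detection.** An assignment qualifies as a putative operon when
all members share a replicon and strand and consecutive members (in genomic
order) are separated by at most `gap_tolerance` intervening genes. The
default of 2 is a design choice: the architecture the model rewards implies
co-transcription, but small unannotated ORFs inside real operons are common,
so zero tolerance is too strict; anything much looser no longer implies a
transcription unit. Genomic member order is *not* required to match the
chain's step order — catabolic operons frequently permute enzyme order —
unless `require_collinear = TRUE`. The operon's 5' member (smallest start on
`+`, largest end on `-`) defines the promoter side.

**4. Regulator search and scoring.** Starting at the operon's 5' member the
scan walks outward on the promoter side only (decreasing index for a
plus-strand operon, increasing for minus) and returns the first
opposite-strand gene whose annotation contains a regulator keyword
(defaults: "regulator", "activator", "repressor"; case-insensitive
substrings, so "antirepressor" matches — a known limitation kept for
simplicity). The pair's score starts at 0 (directly adjacent) and loses one
point per intervening gene on the operon's strand — such a gene may simply
be an operon member the annotation missed — and two points per intervening
gene on the regulator's strand, clamped at −500. The scan runs to the end of
the replicon and the clamp, rather than a search cut-off, enforces the
floor: a very distant regulator is reported at −500 rather than silently
dropped, so the floor value itself is observable in the output. Candidates
are ranked by descending score, with ties broken by organism code and then
regulator locus tag so reruns are byte-identical.

Only CDS features are loaded, so RNA genes and pseudogenes are invisible to
both the gap rule and the intervening-gene count.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `max_len`, `min_len` | —, 2 | chain length window (catalytic steps) |
| `gap_tolerance` | 2 genes | max intervening genes between operon members |
| `keywords` | regulator, activator, repressor | regulator annotation terms |
| `score_floor` | −500 | clamp and report filter for proximity scores |
| `combination_cap` | 50 | gene-copy assignments per organism and chain |
| `chain_cap` | 10,000 | enumeration cap against combinatorial explosion |
| `treat_reversible` | off | also traverse equations right-to-left |
| `require_collinear` | off | member order must equal step order |
| `search_both_sides` | off | also scan the operon's 3' side |

## Dose–response characterisation

Validated candidates are characterised by a reporter dose–response. Raw
plate-reader values are blank-corrected and normalised,
`(F − F_blank) / (OD − OD_blank)`; wells whose corrected OD is not positive
are flagged invalid and excluded. The normalised response is fit with the
four-parameter Hill model

$$y(I) = b_0 + (b_{max} - b_0)\,\frac{I^h}{K_m^h + I^h}$$

by bounded Levenberg–Marquardt least squares (`minpack.lm::nlsLM`).
Initialisation is deterministic: `b0` and `bmax` from the response extremes,
`Km` log-interpolated at half span, `h = 1`, with bounds `h` in (0, 10] and
`Km` in (0, 10 × max dose]. Non-convergence and degenerate inputs (constant
responses, fewer than 5 valid points) return an explicit failure object
rather than an error.

The sensor's **operational range** is the inducer interval spanning 5–95% of
the span above basal. Writing the fractional response
`f = (y − b0)/(bmax − b0)`, the Hill model inverts in closed form:

$$I(f) = K_m \left(\frac{f}{1-f}\right)^{1/h}$$

The fraction is defined relative to the `bmax − b0` span with the basal
level subtracted; this convention reproduces the published bounds for the
two characterised sensors exactly (S-mandelate, `h = 2.13`, `Km = 167` µM →
42–665 µM; phenylglyoxylate, `h = 2.76`, `Km = 93` µM → 32–270 µM, after
rounding to integer µM), which is what validates the choice. When
`hi = 1 − lo` the bounds obey `I(lo)·I(hi) = Km²`.

```{r ranges}
operational_range(km = 167, h = 2.13)
operational_range(km = 93, h = 2.76)
```

## What the simulators emulate

The test surface runs entirely on synthetic inputs generated in code.

* `arabinose_kb()` is the canonical worked example: four reactions from
  β-L-arabinose (C02479) through L-arabinose isomerase (EC 5.3.1.4) and
  ribulokinase (EC 2.7.1.16) to the two epimerase continuations (EC 5.1.3.4,
  EC 5.1.3.22). Enumerating at `max_len = 3` yields exactly three chains —
  one of length 2, two of length 3. Intermediate compound ids use the
  standard compound-id convention; the reaction ids are synthetic fixture
  codes (R9xxxx).
* `simulate_genome()` emits a single-replicon feature table with
  non-overlapping coordinates, planted operon–regulator arrangements and a
  truth table whose expected scores are computed directly from the genome
  spec by
  the deduction formula — independently of the screening code, so end-to-end
  recovery is a genuine check. Decoy annotations come from a keyword-free
  enzyme vocabulary, making false-positive keyword hits impossible by
  construction in negative controls (an adversarial keyword-containing pool
  exists for stress tests). Changing the seed moves coordinates and decoys
  but never the truth.
* `simulate_dose_response()` draws replicate plate readings whose normalised
  response sits on a chosen Hill curve under multiplicative log-normal noise
  with mean one, so expected values stay on the curve.

What passing these tests does **not** show about real data: real genomes
have pseudogenes, RNA genes, nested and overlapping ORFs, annotation
vocabularies far messier than three keywords, and paralog counts that
exercise the combination cap; real knowledge bases contain generic and
protein-bound compounds that are traversed like any other (we do not try to
classify them), and reaction directionality as written is a curation
artifact. The simulators validate the *rules*, not the biology.

## Numerical and design notes

* Scores are integers; clamping uses the floor −500 so the score domain is
  exactly `[−500, 0]`.
* Traversal, ranking and file naming are all deterministically ordered;
  `mine()` reruns are byte-identical on identical inputs.
* Test problem sizes: random-graph oracles use graphs of ≤ 30 reactions;
  score-recount properties use 1,000 random arrangements; Hill parameter
  recovery uses 20 noise seeds at 2% CV over the 7.8–2000 µM dose ladder
  with triplicates. These sizes make the properties sharp while keeping the
  default suite around a minute.
* Regulator search side: the divergent architecture motivates scanning the
  promoter side only; `search_both_sides` exists because the underlying
  heuristic ("nearest regulator in the opposite orientation") does not
  strictly force one side. Ties between equidistant hits prefer the upstream
  side, then the lower start coordinate. For a downstream-side hit the
  intervening genes are counted to the nearest operon member, operon members
  excluded.
* Unknown compounds in lookups return empty results with a logged notice;
  malformed records (duplicate reaction ids, duplicate locus tags, missing
  columns) are hard errors. Absent biology and broken data are different
  conditions and are treated differently throughout.
* The knowledge base is a provider contract: any object exposing the same
  three tables can stand behind it, including a live REST-backed fetcher;
  everything tested here runs on local snapshots and in-memory fixtures.

## Known limitations

* Keyword screening inherits annotation quality; family-specific regulators
  annotated without the three default terms are missed, and "anti-" prefixed
  terms are false positives.
* No operator/binding-site prediction, no promoter or terminator model: the
  gap rule is the entire transcription-unit inference.
* Genome-wide candidate counts depend on the knowledge-base release and
  corpus and are not reproducible at fixture scale; the package's checks are
  property-based instead.
* The regulator protein-sequence deduplication step used in downstream
  candidate triage requires external alignment tooling and is out of scope.
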