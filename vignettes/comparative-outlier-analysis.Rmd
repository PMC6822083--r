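---
title: "Methods: compendium-based expression outlier analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compendium-based expression outlier analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncoutlier)
```

## The problem and the model

A single tumor cannot be tested for "overexpression" in isolation:
overexpressed *relative to what?* `oncoutlier` answers with a compendium —
a large collection of uniformly processed tumor TPM profiles that serves
as the reference distribution for every call. The statistic is
deliberately simple and distribution-free: on `log2(TPM + 1)` values, a
gene in the focus tumor is an outlier when it exceeds the Tukey upper
fence of the reference cohort,

$$x > Q_3 + k \cdot \mathrm{IQR}, \qquad x \ge f,$$

where quartiles are computed by linear interpolation between order
statistics (the "type 7" convention — fixed and documented because
quartile conventions move calls near the fence), $k$ is the fence
multiplier, and $f$ is an absolute expression floor. The floor matters:
among unexpressed genes the IQR collapses and the fence alone would call
meaningless outliers on near-zero expression. Only *over*-expression is
called — the downstream question is druggable overexpression, so the
fence is one-sided. Each call also carries the focus value's percentile
in the cohort, midrank convention (strictly below + half the ties), so a
constant cohort yields 50 and the number reads as "percentile in the
compendium".

Two tracks answer two different clinical questions:

* **pan-cancer** — is this gene extreme against cancer at large? Cohort:
  the whole compendium; universe: the *filtered* gene set, carried as an
  explicit per-gene flag in the annotation (the filtering recipe behind
  such sets is typically not reproducible from published text, so the
  flag is data, never recomputed).
* **pan-disease** — is it extreme even among similar tumors? Cohort: the
  top-`k` compendium samples by Spearman correlation with the focus
  sample over the `n` most-variable genes (variance of log2(TPM+1));
  universe: the full annotation, so tumor-type-specific transcripts are
  retained. Rank correlation over variable genes is the standard
  expression-similarity practice: robust to scale, dominated by genes
  that actually vary. Ties in correlation break by sample id, making the
  cohort deterministic; a focus sample present in the compendium is
  excluded from its own cohort.

The three lists (pan-cancer, pan-disease, intersection) are each
intersected with the curated actionable-gene table and each tested for
gene-set overlap by the hypergeometric upper tail with
Benjamini–Hochberg control. Enrichment p-values are universe-sensitive,
so each track's enrichment runs against its own universe (filtered for
pan-cancer and for the intersection list, which is a subset of the
pan-cancer list; full annotation for pan-disease) and the universe size is
recorded in every result row.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `iqr_multiplier` | 1.5 | — | the classical boxplot fence; larger is stricter |
| `min_log_expression` | 2.5 | log2(TPM+1) | floor suppressing outliers among unexpressed genes (~4.7 TPM) |
| `min_cohort_size` | 20 | samples | quartiles on fewer samples are too noisy to fence |
| `cohort_k` | 100 | samples | pan-disease cohort size; large enough for stable quartiles, small enough to stay "similar" |
| `n_variable_genes` | 1000 | genes | similarity ranking over informative genes only |
| `q_cut`, `max_report` | 0.05, 100 | — | report sets with FDR below 5%, first 100 |
| QC `min_expressed_genes` | 10,000 | genes | permissive library-breadth screen; the rule applied is echoed into every report |

The original study's exact fence, similarity construction and QC
thresholds live in protocols that are not printed; the defaults above are
this package's documented stand-ins, exposed as data (`outlier_params()`,
`qc_rule()`) rather than buried in code, and echoed into provenance on
every run.

## What the synthetic generator emulates — and what it does not

`simulate_compendium()` draws `log2(TPM+1)` from a normal law per
(disease, gene): a shared baseline plus a per-(disease, gene) offset drawn
once at compendium creation and stored, so focus samples simulated later
are exchangeable with compendium members of the same disease. Values are
truncated at zero and back-transformed, giving the right-skewed,
nonnegative TPM distributions seen in practice. Defaults (chosen once):
baseline mean 3 and SD 0.8 in log2 units — a typical within-disease
dispersion for expressed genes in uniformly processed tumor compendia —
disease-offset SD 1, a 16.4% expected pediatric fraction (the pediatric
share of a realistic reference compendium), and 46% of genes flagged into
the filtered universe (the approximate ratio of a filtered ~27k-gene set
to a full ~58k-gene annotation). Ages are uniform on [0, 30) for
pediatric draws and [30, 80) otherwise: only the under-30 fraction enters
any implemented statistic.

The generator is a study-conditions machine, not a cohort estimate: it
has no isoforms, fusions, batch effects, library-size artifacts, or
heavy-tailed per-gene noise. Passing tests therefore demonstrate that the
*machinery* (fences, similarity ranking, enrichment, classification)
behaves as specified under a controlled model — not that real tumors meet
any particular sensitivity. `simulate_dna_findings()` constructs DNA and
RNA findings jointly with a known Venn cell per sample, so concordance
classification can be verified against construction rather than against
re-derived truth.

## Numerical and design choices

* **Quartiles**: `stats::quantile(type = 7)`; verified in tests against an
  independent sort-and-interpolate oracle to 1e-9 on random cohorts. With
  cohort log values $\{1..8\}$ the fence is $6.25 + 1.5 \times 3.5 = 11.5$:
  a focus value of 12 is an outlier, 11 is not — the tests pin exactly
  this boundary behaviour.
* **Hypergeometric tail**: `stats::phyper` with an `overlap - 1` lower
  bound; verified against exhaustive enumeration of all draws for every
  margin with universe $\le 12$. `P(X \ge 0) = 1` by convention.
* **BH**: `stats::p.adjust(method = "BH")`, verified against the written
  out step-up recursion; permutation-equivariant by construction.
* **Tie-breaks**: enrichment results sort by `(q, p, set name)`; cohort
  similarity ties break by sample id; drug annotations order by source
  then drug — every ordering is total, so outputs are byte-reproducible
  across runs and platforms (the determinism test compares files byte by
  byte). For the same reason report provenance records a config hash and
  package versions but no wall-clock timestamp.
* **Degenerate inputs**: constant cohorts produce a fence equal to the
  value (strict inequality, no call); empty findings and empty gene lists
  flow through as empty tibbles, never errors; an empty cohort summary is
  an error because percentages of zero samples are undefined; unknown
  allele-expression status never deprioritizes a DNA finding ("no
  evidence" is not "evidence against").
* **Symbol matching** is exact after uppercasing; aliases belong in the
  data files. The curated tables (92-gene actionable list with 37 direct
  and 55 indirect entries, drug–gene rows restricted to four curated
  cancer sources, pathway-group map) ship as synthetic, code-built
  fixtures with real oncology gene symbols; the real curated exports drop
  in as TSVs with the same columns.
* **Concordance rules**: `support` needs exactly one actionable DNA gene
  with expression support (itself an outlier, or a downstream pathway
  group enriched); `prioritize` needs two or more with at least one
  supported; `deprioritize` needs a mutant allele known unexpressed *and*
  no support; `rna_only` and the RNA-only Venn cell imply each other.
  Downstream gene-to-pathway links are a data file seeded with
  well-established links (e.g. activated RAS to cell-cycle and
  BCL2–MDM2 programs; BCR–ABL1 to PI3K/AKT/mTOR and B-cell receptor
  signaling): an absent mapping row means no downstream support can be
  claimed — deliberately conservative.
* **Percentages** round half-up to one decimal (`round_half_up()`), the
  convention of clinical reporting; base R's round-half-even would print
  68.75% as 68.8 only by accident of floating point.

## Problem sizes used in the test suite

The suite verifies calibration and recovery by Monte Carlo at sizes
chosen to make the checks sharp but quick: fence-oracle agreement on 200
random cohorts; the full hypergeometric enumeration sweep at universe
$\le 12$; spike recovery (+4 log2) and null calibration against a
500-sample single-disease compendium over 100 seeded replicates —
sensitivity $\ge 0.95$ with a per-gene null outlier rate $\le 2\%$ at
default parameters (the fence's theoretical null exceedance on normal
data is about 0.35%, plus the floor); pan-disease cohort purity on a
3-disease, 150-sample compendium over 50 replicates; concordance recovery
on 740 constructed samples with the mixed-cell construction; and
end-to-end byte-determinism on a 200-gene, 80-sample fixture workspace.
`tests/testthat/test-acceptance.R` holds these cohort-level checks; the
same quantities are recomputed by `scripts/acceptance.R`.

## Known limitations

* The fence and floor are heuristics; no per-gene error model or
  multiple-testing control is applied at the *outlier* stage (control
  enters only at enrichment). This mirrors how single-sample outlier
  tools are actually used, but means the per-gene false-positive rate is
  a property of the data's tail, not a guaranteed level.
* Pan-disease cohort quality degrades when the compendium contains few
  truly similar tumors; the cohort's disease composition is recorded
  precisely so a reviewer can see when the "most similar" set is not.
* Underexpression, fusions, allele-specific expression and differential
  expression between groups are out of scope.
* The synthetic generator's normality means tests cannot detect
  misbehaviour specific to heavy-tailed real data.
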