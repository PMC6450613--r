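---
title: "Methods: SNP array design and evaluation with charrpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNP array design and evaluation with charrpanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`charrpanel` turns the design of a high-density SNP genotyping array into a
deterministic, auditable pipeline. This vignette documents the underlying
models, the tunable parameters and their defaults, the choices made where
the design space was genuinely open, and what the synthetic-data module
does and does not emulate.

All genomic coordinates in the package are 1-based and inclusive, the
VCF/GFF convention. Genotypes use two-symbol coding (`aa`/`ab`/`bb` with
`a` the reference allele, `--`/`NA` missing); a VCF `GT` adapter covers
interchange. Every stochastic function takes a mandatory `seed` and leaves
the session RNG untouched, so identical inputs always give byte-identical
outputs.

## Discovery QC models

**Family filters.** Markers genotyped in full- or half-sib families are
checked three ways, and a marker is removed only when it fails a criterion
in *every* family in which it is testable — a deliberate conservatism: a
marker that behaves in one family is likely assayable, and family-specific
failure often reflects that family's DNA quality rather than the marker.

* *Missingness*: fail when the missing fraction among progeny is strictly
  greater than `max_missing` (default 0.5).
* *Mendelian errors*: a progeny genotype is erroneous when it cannot be
  composed of one allele from each recorded parent. The rule is full
  transmission consistency — the classic instance is `bb` progeny under an
  `aa x ab` cross, but the general rule also catches, say, `ab` under
  `aa x aa`. Missing genotypes never count. By default one flagged cell
  fails the marker (`tolerance = 0`), since a single genuine transmission
  error implies the assay resolves clusters poorly.
* *Segregation distortion*: a chi-square goodness-of-fit of non-missing
  progeny counts against the cross's Mendelian expectation (`aa x ab`:
  1:1 over `aa`/`ab`; `ab x ab`: 1:2:1; `ab x bb`: 1:1 over `ab`/`bb`).
  Crosses with both parents homozygous are reported "not testable".
  Progeny genotypes outside the expected classes are transmission errors,
  not distortion, and are excluded from the counts. The default
  `alpha = 0.01` is a pragmatic screening level; no multiple-testing
  correction is applied by default (a Bonferroni flag exists) because the
  screen is intentionally liberal — a distorted marker that slips through
  is caught later by array-performance classification. Whether the test
  should pool counts across families or test each family separately is not
  dictated by the biology; both are provided (`pooled`), with per-family
  testing plus the all-families rule as the default.

**Population filter.** MAF is computed by direct allele counting over
non-missing genotypes and compared inclusively (`MAF >= 0.05`). Note one
asymmetry kept on purpose: the GBS *prioritisation* criterion (b) uses a
strict `MAF > 0.05`. The two thresholds express different intents
(discovery-stage retention vs. extra credit for clearly-polymorphic
markers) and both boundaries carry dedicated unit tests.

**High-coverage record filters.** Two stages with all boundaries
inclusive: calling (`QUAL >= 20`, `MQ >= 30`, `GQ >= 20`,
`1 <= DP <= 100`) and design (`5 <= DP <= 45` plus the same quality
floors). The tighter design-stage depth window drops both low-confidence
calls and likely collapsed paralogs — important in salmonids, whose
ancestral genome duplication leaves many two-copy regions. Records missing
a required annotation get an explicit "not testable" status; nothing is
silently passed.

**Placement uniqueness.** Candidates must place exactly once in the
assembly. Placement is exact substring matching of the flank-with-allele
sequence and its reverse complement across all sequences, counting
overlapping hits; a palindromic query is counted once per physical locus,
as an aligner would report it. Exact matching (rather than a mismatch-
tolerant mapper) is deterministic, dependency-free, and adequate at the
scales the package targets; true mapping with mismatches/indels is out of
scope and would be the one component to swap when applying the pipeline to
a full-size genome.

## Cross-validation and tiering

Candidates from two platforms validate each other when they share sequence
name, position and unordered allele pair. Positions carrying conflicting
allele pairs within one platform (multi-allelic collisions) are excluded
from matching and logged. "Detected in two populations" (GBS criterion a)
is interpreted as presence in both populations' call sets, not
polymorphism in both — detection itself is the evidence the criterion
rewards.

Strand-ambiguous SNPs (A/T, C/G) read identically on both strands and
need twice the assay real estate on hybridisation arrays, so they are
removed — except for sources explicitly exempted, the mechanism for
boosting a population whose marker yield would otherwise be poor.

## Panel assembly

The fill order is fixed and deterministic: tier 1 entirely, tier 2 (sdY)
entirely, tier 3 spacing selections, tier 4 filler until the budget is
exactly met or pools are exhausted. The spacing rule partitions each
sequence into consecutive windows of the target width (900 kb for rare
SNPs, 62 kb for common intergenic SNPs) anchored at bp 1 and takes the
best-ranked candidate per nonempty window; consequently consecutive picks
are < 2x the target apart whenever intervening windows hold candidates. A
strict-greedy alternative ("next candidate at least the target past the
last pick") is available behind `method = "greedy"`. The windowed rule was
chosen as the default because it is order-independent within windows,
trivially parallel over windows, and easy to verify by a brute-force gap
scan.

Ranking is fully deterministic: external conversion score (descending),
then `|AF - 0.5|` (ascending), then position, then id. The rare pool spans
genic and intergenic SNPs while the common pool is intergenic-only —
rare-variant coverage is scarce enough that gene overlap should not
disqualify it, whereas common SNPs are abundant enough to reserve
transcript-resident ones for the gene-representation goal.

The external conversion score is modelled as a supplied per-candidate
number with a three-level label (`recommended`/`neutral`/`not_recommended`);
the package never attempts to re-derive such proprietary in-silico assay
scores. When labels are present, `not_recommended` candidates are dropped
from the optional pools and a top-up pass from the remaining common
intergenic pool refills the freed budget, emulating a design resubmission.

Probes are emitted in bracket notation (`35bp [REF/ALT] 35bp` for the
71-mer with the SNP at bp 36; `50bp [REF/ALT] 50bp` for the 101-mer used
in transcript comparison), flanks cut from the forward strand. sdY sexing
markers bypass AF and spacing rules entirely and are flagged — not
dropped — if their flanks are short, because a sexing assay with imperfect
chemistry still beats no sexing assay.

## Post-genotyping evaluation

Axiom's internal cluster-resolution metrics are proprietary, so marker
classification here is a *surrogate* that uses only observable facts: the
call rate and the observed genotype classes. `CallRateBelowThreshold`
below 0.97 call rate; otherwise `MonoHighRes` (one allele observed),
`NoMinorHom` (heterozygotes but no minor-allele homozygote) or
`PolyHighRes` (both homozygote classes). "Recommended" is derived as
"not call-rate-failed and not otherwise flagged", and "polymorphic" is
`PolyHighRes` or `NoMinorHom`. Sample QC uses strict thresholds as
printed in array best-practice workflows: sample call rate `> 0.97`,
passing-sample mean `> 0.98`, and an optional pre-supplied dish-QC
boolean (`> 0.82` upstream).

Sharing reports are exact set algebra over marker ids (all `2^k - 1` Venn
regions); percentages throughout are printed to one decimal using R's
round-half-even. Coverage windows are consecutive fixed-width segments
anchored at bp 1 per chromosome, the truncated final window counting as a
window; per-chromosome density is `count / (length / 10^6)` and the mean
gap is `length / count`. A gene is represented when at least one panel
marker lies within its inclusive `[start, end]`.

Genotypic sexing exploits male-limited *sdY* biology: the marker is
modelled as presence/absence (calls in males, no-calls in females) rather
than allelic variation, and a sample is predicted male when at least
`min_called` (default 1) of the sdY assays yield a call. The default of 1
maximises sensitivity; raising it trades sensitivity for robustness to
stray calls.

## The synthetic-data module

The generators emulate, with controllable and seeded structure: a
multi-chromosome genome with unplaced contigs; true SNPs at a chosen
density with per-group allele frequencies (uniform, beta or point-mass);
platform call sets containing a detection-probability thinned copy of the
truth plus platform-private false positives with their own DP/QUAL/GQ/MQ
and binomially-estimated AFs; family genotypes with injected Mendelian
errors, missingness and segregation distortion; and a post-design array
run with Hardy-Weinberg genotypes per group, failed markers, per-sample
call-rate variation and sdY presence/absence.

Distortion is modelled as exponential tilting of the Mendelian class
probabilities — class weight `exp(strength * n_b_alleles)` — because a
single knob smoothly nests the null at strength 0. Two consequences are
worth knowing. First, tilting preserves the ratio
`p(ab)^2 / (p(aa) p(bb)) = 4`, so some arbitrary distorted trinomials
(e.g. 40:40:20) are not exactly representable; the package's power checks
therefore measure the tilting model at its default strength `log(2)`
(noncentrality about 23.5 at n = 100 on an `ab x ab` cross, power about
0.97 at `alpha = 0.01`), while the canonical worked chi-square example for
observed counts (40, 40, 20) — statistic 12.0 — is asserted exactly as
arithmetic. Second, injected Mendelian "errors" that land on a genotype
still consistent with the parents (always possible under `ab x ab`) are
undetectable in principle; sensitivity is defined, and verified to be 1.0,
over the *detectable* error cells.

Default magnitudes — Mendelian error rate 0.01, missingness 0.05,
distorted fraction 0.05, platform detection probabilities 0.90/0.25/0.20/
0.15 (high-coverage/GBS/RAD/RNA-seq) with false-positive rates of
0.10/0.02/0.02/0.01 per kb and AF-estimation sample sizes 8/48/60/18 —
are free parameters chosen as plausible for reduced-representation and
whole-genome data of this kind, not estimates of any particular dataset.
False positives carry true AF 0 in every group, which is what makes
conversion-to-polymorphic rates realistic: putative markers that were
sequencing artefacts become monomorphic assays.

What the generator does *not* emulate: read-level data (no FASTQ, no
sequencing-error model), linkage disequilibrium between markers,
population structure beyond independent per-group AFs, and assay-chemistry
covariates of conversion failure. Passing tests therefore demonstrate the
correctness of the pipeline's logic and arithmetic and its statistical
calibration under the stated models — not performance claims about any
real genotyping platform.

## Numerical and testing choices

Chi-square tests use `stats::chisq.test` with the expected-class
probabilities; "not testable" is a first-class status everywhere
(uninformative crosses, all-missing markers, absent quality fields) and is
never conflated with pass or fail. Ties in spacing/filler ranking are
broken by score, AF distance to 0.5, position, then id, making reruns
bit-identical; the pipeline's determinism is verified by checksum
comparison of complete output directories.

The bundled study sizes keep the full suite fast while leaving the
statistical checks well-powered: synthetic genomes of 2-3 chromosomes at
50-200 kb plus a handful of contigs, ~2 SNPs/kb, families of 15-100
progeny, 2,000 null markers for the type-I-error check (3-sigma binomial
bands), 1,000 random queries for the placement cross-check, and array runs
of tens to hundreds of samples. These sizes are the package's chosen study
conditions; all thresholds and seeds are fixed in code, not tuned per run.

## Known limitations

* Exact-match placement counting does not model mismatch-tolerant mapping;
  repeat-rich real genomes need an external aligner at this step.
* The Axiom-style classifier cannot see cluster geometry; markers that a
  real workflow would flag as `Other`/off-target appear here only through
  call-rate failure.
* The sdY model is binary; partial hybridisation or cross-amplification in
  females is not simulated.
* Family QC assumes known, correct parent genotypes; pedigree errors
  masquerade as Mendelian failures.
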