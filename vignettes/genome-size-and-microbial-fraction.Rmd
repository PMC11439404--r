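---
title: "Estimating community genome size and the microbial fraction of metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating community genome size and the microbial fraction of metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agsmf)
```

## The estimation problem

Shotgun metagenomes of soil mix bacterial and archaeal DNA with substantial
amounts of eukaryotic and viral DNA. Estimators of community average genome
size (AGS) that divide the number of reads by the number of single-copy
marker genes detected implicitly assume all reads are microbial, so every
non-microbial base pair inflates their numerator. `agsmf` implements the
coverage-based alternative: price each taxon in a marker-derived community
profile at a reference genome size and weight by its fold-coverage. Because
eukaryotic reads are simply never recruited by bacterial/archaeal markers,
they change neither the coverages nor the weights, only the denominator of
the *microbial fraction* (SMF).

The pipeline has four stages, each usable on its own:

1. a genome-size-annotated taxonomy built from reference genome metadata
   (`build_taxonomy()`),
2. per-sample coverage profiles (`read_profiles()`, `merge_runs()`),
3. per-sample estimates: AGS, SMF, non-microbial fraction, known-species
   fraction, per-domain coverage shares (`estimate_all()`),
4. a Gamma GLM of AGS on soil pH (`fit_gamma_glm()`, `grouped_fits()`).

## Reference genome sizes

**Correction.** Completeness and contamination estimates (e.g. from
single-copy-gene QC tools) describe, respectively, the fraction of a genome
recovered in an assembly and the fraction of the assembly that is
extraneous. We first remove the estimated contaminant bases, then rescale
by the recovered fraction:

$$\text{corrected} = \text{assembly\_size} \times
  \frac{1 - \text{contamination}/100}{\text{completeness}/100}.$$

Published descriptions of this correction cite the concept without printing
a formula; removing contamination before rescaling for incompleteness is
the least surprising composition of the two adjustments, and the formula is
isolated in `corrected_genome_size()` so an alternative can be swapped in
one place. Contamination ≥ 100% or completeness ≤ 0 are rejected rather
than clamped. Completeness near its lower bound dominates the correction (a
70%-complete assembly is scaled up by 1.43×), which is why the simulator
draws completeness from U(70, 100): below ~50%, published size corrections
of this form become unreliable and such genomes are usually excluded from
reference databases anyway.

**Species and higher ranks.** A species' AGS is the arithmetic mean of the
corrected sizes of *all* genomes assigned to it — the mean over conspecific
genomes, rather than a single representative genome, is the less arbitrary
choice when a species has several assemblies of varying quality. Above the
species level, AGS is propagated **level-wise**: every internal node is the
unweighted mean of its immediate children, so a family is the mean of its
genera, not of all its descendant species. The two definitions differ
whenever genera have unequal species counts; the level-wise rule treats
sibling taxa as exchangeable units instead of letting a heavily sequenced
genus dominate its family. A synthetic root node above the domains carries
the mean of the domain AGS values so that even entirely unresolved coverage
can be priced.

**Lookups.** Profiles can assign coverage at any rank. `lookup_ags()`
returns the AGS of the deepest matching node; if the exact taxon is missing
from the database (common when a small reference is paired with a broad
profile) it falls back to the deepest *present* ancestor and warns, rather
than erroring — a lineage whose domain is unknown is still an error, since
there is no defensible price for it.

## Per-sample estimates

For a profile with coverages $c_i$ and looked-up sizes $s_i$:

* $\mathrm{AGS} = \sum_i c_i s_i / \sum_i c_i$ — invariant to rescaling all
  coverages, hence to sequencing depth and to the non-microbial share;
* microbial base pairs $= \sum_i c_i s_i$; $\mathrm{SMF} = 100 \sum_i c_i
  s_i / \text{total\_bases}$, capped at 100% with a warning (coverage noise
  can push the prediction past the total; percentages above 100 are not
  meaningful), and the non-microbial fraction is $100 - \mathrm{SMF}$;
* the known-species fraction is the coverage share of entries resolved to
  species rank, over **all** entries including root-level coverage;
* per-domain fractions are computed over domain-assigned coverage only
  (root-level coverage is excluded from numerator and denominator, since it
  cannot be attributed to either domain).

Root-assigned coverage *is* counted as microbial in AGS and SMF: in
marker-based profiling, coverage at the root is still recruited by
bacterial/archaeal markers — it is unresolved, not non-microbial.

Percentages are carried on the 0–100 scale everywhere, including files;
genome sizes are held in base pairs as doubles and rendered as Mbp (1
decimal) only for display. Dataset summaries report both mean and median
for every statistic — genome sizes are conventionally summarized by means,
skewed fractions by medians — so `summarize_estimates()` computes both and
lets the caller quote the appropriate one.

## The pH association

`fit_gamma_glm()` fits `ags ~ ph` with a Gamma response via `glm()` —
genome sizes are strictly positive and right-skewed, which is exactly the
Gamma family's territory — with IRLS convergence at a relative deviance
change of 1e-8 or 100 iterations (non-convergence is flagged on the result
and warned about, never silent). The default link is the canonical
`inverse`; `log` is available and often more interpretable (the slope is a
per-pH-unit log-fold change in mean AGS). Explained variation is reported
as the deviance pseudo-R², $1 - D_{res}/D_{null}$, with the squared
observed–fitted correlation alongside for transparency; a constant response
has zero null deviance and is reported as pseudo-R² 0. The Pearson estimate
of dispersion is reported but affects neither coefficients nor pseudo-R².
`grouped_fits()` repeats the fit within groups (n ≥ 3; smaller groups are
skipped with a warning) next to the pooled fit, tabulating slope signs —
the relevant check when asking whether an association holds *within* soil
types and not only across them.

Two helpers cover the comparison arithmetic of dataset-level reports:
`fold_underestimate(observed, c(low, high))` divides an observed percentage
by the ends of an assumed range (1-decimal rounding), and
`percent_difference(reference, other)` computes
$100\,|ref - other|/ref$ rounded to an integer. The reference is an
explicit argument because "X% lower than A" and "X% higher than B" use
different denominators, and guessing the intended one from context is
exactly how such comparisons go wrong.

## The synthetic-data generator

`simulation_spec()` fixes the study conditions; `simulate_taxonomy()` and
`simulate_sample()` realize them with exact bookkeeping:

* **Genome sizes** are lognormal, `meanlog = log(4e6)`, `sdlog = 0.4`
  (roughly 1.5–11 Mbp — realistic for soil bacteria). Completeness and
  contamination are drawn U(70, 100) and U(0, 10), and the emitted assembly
  size is *back-computed* so that `corrected_genome_size()` returns the
  drawn true size exactly — the correction round-trips by construction and
  every downstream truth is exact.
* **Abundances** are lognormal (`sdlog = 1`) cell abundances; coverage is
  proportional to abundance and scaled so that microbial base pairs equal
  `(1 − euk_fraction/100) × total_bases` exactly. Eukaryotic DNA is
  modelled *only* as those unattributed bases — no eukaryotic lineages are
  emitted, mirroring what marker-based profiles can see. Default
  `euk_fraction` is 38.8% and `total_bases` 1 Gbp, a typical soil
  metagenome with a large non-microbial share.
* **Archaea** receive exactly `archaea_fraction` (default 1.2%) of the
  microbial coverage, with ~5% of species placed under `d__Archaea`.
* **Partial resolution**: each entry's lineage is truncated one rank with
  probability `truncation_prob` (default 0.3), repeatedly — a geometric
  law under which ~70% of coverage stays at species rank and a small tail
  reaches the root. Real soil profiles are far less resolved; the tests
  that depend on resolution set this parameter explicitly rather than
  relying on the default.
* **Noise**: multiplicative lognormal coverage noise (`sd = 0.1` by
  default); the recorded truth is always the exact pre-noise state, and
  with noise and truncation disabled the emitted profile reproduces the
  truth to machine precision.

Determinism: every generator takes an explicit integer seed;
`simulate_dataset()` seeds sample *i* with `seed + i` so samples are
independent but reproducible, and the CLI's `simulate` subcommand records
the seed and full spec in a manifest.

`simulate_ph_dataset()` generates the association benchmark directly:
pH ~ U(3.5, 9), mean AGS through the chosen link (`exp(15.5 − 0.15 ph)` bp
by default, i.e. ~3.2 Mbp at pH 7 falling with pH), Gamma noise with shape
20, and round-robin environment labels. `reads_per_marker_foil()` is the
analytic counterpart of a total-reads-per-marker estimator: its expected
value is the true AGS inflated by $1/(1 - euk/100)$. It exists purely as a
foil — the property the test suite demonstrates is that the
coverage-weighted AGS is *constant* in the eukaryotic fraction while the
foil inflates by exactly that factor.

**What the generator does not emulate.** No read-level simulation
(sequencing error, GC bias, assembly artifacts), no misassigned coverage
(truncation loses resolution but never attributes coverage to the wrong
clade), no correlation between genome size and abundance, and no eukaryotic
lineages in profiles. Passing tests therefore show the *estimator algebra*
is correct under the stated statistical structure; they do not validate
marker-gene profiling itself, and accuracy on real data is bounded by the
profiler and reference database used upstream.

## Numerical and test-design choices

* Taxonomy propagation is validated against a brute-force recursive-mean
  oracle on random taxonomies of up to 20 species (100 seeds), at 1e-9
  relative tolerance; TSV round-trips write doubles with `%.17g` so node
  values reproduce exactly.
* Recovery tests run noise-free at `euk_fraction ∈ {0, 20, 40, 60, 80}`,
  where non-microbial estimates must equal truth exactly and AGS to 1e-9
  relative; noisy recovery (sd 0.1) is checked in expectation across seeds.
* GLM parameter recovery uses 20 replicates at n = 300 (log link, slope
  −0.15, shape 20) — sizes chosen so the whole suite runs in seconds on one
  CPU. The replicate-mean slope is required to sit within **3 standard
  errors** of truth: with 20 replicates a 1-s.e. band would reject an
  exactly unbiased estimator about a third of the time by construction,
  whereas 3 s.e. keeps the false-alarm rate near 0.3% while still detecting
  any bias comparable to a single fit's standard error (the measured bias
  is about a quarter of one replicate-mean s.e.). Slope-sign recovery
  (≥ 19/20 replicates) and a null-model check (mean pseudo-R² < 0.02 when
  the generating slope is 0) accompany it.
* Ties and degenerate inputs: empty profiles error in AGS (undefined
  weighted mean) but contribute 0 microbial bases; zero-coverage entries
  are dropped on load; a constant response yields slope 0 and pseudo-R² 0;
  groups below n = 3 are skipped, not fit.

## Limitations

* Run merging operates on coverage profiles (coverages summed per lineage,
  total bases summed). Pipelines that merge raw marker-OTU tables and then
  re-profile can differ if their profiling step is non-linear in the merged
  counts; under additive coverage the two are equivalent.
* `total_bases` is metadata (or `read_count × mean_read_length`), not
  computed from sequence files — FASTQ handling is out of scope.
* The level-wise propagation rule and the correction formula are stated
  conventions, not the only defensible ones; both are isolated behind
  single functions so alternatives are one-line changes.
* The known-species fraction is coverage-weighted; genome-equivalent
  definitions (weighting by cell counts or by base pairs) give different
  numbers on the same profile.
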