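---
title: "Paired differential m6A analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired differential m6A analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m6adiff)
```

## The problem

Nanopore direct-RNA sequencing lets a modification caller report, for every
candidate N6-methyladenosine (m6A) site, how many of the reads covering the
site carry the modification. `m6adiff` takes those per-site tables for a
*paired* design — each patient sampled before and after a treatment — and
answers the questions such a study asks: which sites changed, where they sit
in gene models, whether the genes carrying them also changed expression, and
whether their transcripts' poly(A) tails (a proxy for mRNA stability)
shortened.

The motivating setting is hypomethylating-agent therapy in acute myeloid
leukemia, where a handful of patients yield matched leukemic and remission
bone-marrow samples; the methods are generic for any small paired pre/post
design with per-site modification counts.

## Site-level model

A site's m6A **ratio** (stoichiometry) is the binomial proportion

$$\hat r = m / n,$$

with $m$ modified and $n$ total reads. We treat $m \sim
\mathrm{Binomial}(n, r)$, so $\hat r$ is unbiased with standard error
$\sqrt{r(1-r)/n}$ — about 0.05 at the ~100x coverage the package's
simulations assume. Sites with fewer than `min_coverage = 10` reads in any
sample are excluded from inference: below that, $\hat r$ is too coarse to
support a ratio comparison. A site is labeled "high-level" when $\hat r$ is
*strictly* greater than 0.5, i.e. a majority of transcripts carry the mark.

## The paired differential caller

For each patient $k$ the caller forms the ratio difference
$\Delta_k = \hat r^{\text{post}}_k - \hat r^{\text{pre}}_k$ at every site
covered in both members of the pair; positive $\Delta$ means m6A went up
after treatment. Sites covered in every pair are tested with a one-sample
t-test of the $\Delta_k$ against zero ($t = \bar\Delta / (s_\Delta
/\sqrt{K})$, $K-1$ degrees of freedom, two-sided by default). A site is
**called** when

1. $p < \alpha$ (default $\alpha = 0.1$ on the raw p-value, no
   multiple-testing correction — a BH-adjusted column is emitted for
   transparency but never used for calling), and
2. the deltas have the same strict sign in **every** pair (the direction-
   consistency filter).

Zero-variance sites (identical deltas in all pairs) have an undefined t
statistic and are excluded with a logged count rather than given an
artificial p-value; inflating the variance by an epsilon would manufacture
significance for lattice artifacts of the binomial counts.

### What the consistency filter does and does not do

A fact worth knowing when exactly three pairs are available: the largest
$|t|$ a mixed-sign delta triple can produce is 2 (approached by
$(-a,-a,\varepsilon)$ as $\varepsilon \to 0^+$), while the two-sided
$p<0.1$ critical value at 2 degrees of freedom is $t^* = 2.92$. Every site
passing the p-gate therefore already has sign-consistent deltas, and the
filter is mathematically redundant at these defaults — the called set
equals the $p<\alpha$ set. The filter becomes a real constraint with four
or more pairs (where mixed-sign $|t|$ can reach 3 against a critical value
of 2.35), with one-sided testing, or with larger $\alpha$. The test suite
pins both facts: a property test that mixed-sign triples never reach
$|t| = 2.92$, and a four-pair case where a significant but inconsistent
site is rejected.

### Error properties of the raw-P rule

Because calling uses an uncorrected $p < 0.1$ gate, roughly 10% of truly
unchanged sites are called (the suite measures ~0.10 on 10,000 null sites
at 100x). Power at the simulated effect size is essentially 1: a ratio
drop of 0.4 at 100x coverage gives an expected $t \approx 9.9$. The flip
side is false-discovery behaviour: when true effects are sparse — 100
planted among 1,000 sites — about 90 false calls accompany ~100 true ones,
an FDR near 0.5. The procedure is therefore a per-site error-rate rule,
not an FDR-controlled one; it is defensible when treatment effects are
dense (a globally demethylating drug) and candidate lists are validated
downstream, and the emitted BH column is the remedy when they are not.
This is a property of the calling rule itself, reproduced faithfully here;
the acceptance suite reports it without adjustment.

## Annotation

Sites are intersected with gene spans under half-open containment
($\text{start} \le \text{pos} < \text{end}$, all coordinates 0-based
half-open internally; 1-based input dialects are converted at the
boundary). Intersection is strand-aware by default because direct-RNA
reads are stranded; `ignore_strand = TRUE` reproduces the behaviour of
coordinate-only interval tools. Within a gene, a site's functional region
is resolved across transcripts with the precedence

> 3'UTR > 5'UTR > CDS > non-coding exon > intron,

so a site exonic in any isoform is never labeled intronic, and the 3'UTR —
where m6A concentrates and where the headline localization claims live —
wins ties. Positions inside a gene span but outside all transcript
features fall back to `intron`. UTRs absent from the annotation are
inferred from CDS boundaries (exonic sequence outside the CDS span, split
by strand); explicit and inferred UTRs are never mixed within one
transcript.

Gene-level rollup of site calls is deliberately conservative: a gene is
m6A-down when it owns at least one called-down site and *no* called-up
site (symmetrically for up); genes with calls in both directions are
quarantined as `mixed` so the up/down gene sets stay disjoint, which the
downstream Venn construction requires.

## Expression and integration

Counts are scaled to counts-per-million (CPM) per sample; the DEG test
operates on $\log_2(\mathrm{CPM} + 1)$, the pseudo-count handling zeros. With
matched pairs the test is a paired t-test on per-patient log differences,
otherwise Welch's. A gene is differentially expressed at $|\log_2
\mathrm{FC}| > 1$ and $p < 0.05$ (fold-change threshold 2). With three
pairs this test has 2 degrees of freedom; at negative-binomial dispersion
0.1 its power against a 4-fold change is only ~0.7, which is the honest
cost of the smallest paired design — the package reports it rather than
substituting a different test, since the simplest test consistent with the
study's statistics is the point of comparison. Moderated alternatives
(limma, DESeq2) are deliberately out of scope for the calling path.

The integration step intersects the m6A gene sets with the DEG sets;
`concordant_down` (m6A down *and* expression down) is the
candidate-biomarker class. Venn counts satisfy inclusion–exclusion exactly
by construction, and the suite asserts it.

Note one practical caveat baked into the synthetic design: per-million
scaling is compositional, so a few extremely up-regulated high-abundance
genes can depress every other gene's apparent expression. The generator
therefore plants up-regulated genes at low baselines (transcripts switched
on by treatment) — a realistic choice that also keeps the library-size
shift small. With composition-heavy real data a ratio-based normalization
would be the first thing to swap in.

## Poly(A) comparison

Tail lengths are compared per read (nanopore tail estimates are per-read)
with a two-sided Mann-Whitney U test per gene — tail distributions are
skewed, so a rank test rather than a t-test. Genes with fewer than 3 reads
in either group are skipped with a recorded reason; all-constant
comparisons are degenerate with $p = 1$. Batch results carry BH q-values.

## The synthetic study generator

Every pipeline input can be simulated with planted, recorded truth, so each
stage has a recovery test without any external data. The generator's
defaults *are* the study conditions the analyses assume:

* **Design**: 3 patients x pre/post; 300 genes (87% protein-coding, the
  protein-coding share reported for m6A-carrying genes in this setting) on
  5 chromosomes; genes of 1-3 transcripts with explicit exon/CDS/UTR
  features, extra isoforms dropping one internal exon.
* **Sites**: ~1,400 RRACH sites with the 12 variants at designed
  frequencies (AAACA most, AGACA least abundant, mirroring the observed
  ranking); functional-region placement 55/25/10/10 across
  3'UTR/CDS/5'UTR/intron (3'UTR-dominant); per-sample coverage
  negative-binomial with mean 100 (floor 20); modified counts binomial
  around the true stoichiometry.
* **m6A effects**: 40 down / 8 up genes, every site of an affected gene
  shifted by $\mp 0.4$ — the package's nominal detectable effect at 100x,
  where the per-site expected $|t|$ is ~10.
* **Expression**: negative-binomial counts, dispersion 0.05 (paired
  same-patient libraries are close to technical replicates), 30 down / 15
  up genes at $|\log_2\mathrm{FC}| = 5$. The magnitude is a design choice
  made from a power analysis of the 2-degree-of-freedom paired test:
  remission-versus-leukemia marrow involves order-of-magnitude collapses
  of blast-restricted transcripts, and at this effect size per-gene power
  is ~1 and the expected number of false concordant genes is well below
  one, so the 13 planted concordant-down genes (the intersection of the
  m6A-down and expression-down sets by construction) are exactly
  recoverable.
* **Poly(A)**: log-normal tails, median 120 nt, log-sd 0.35; 3 of the
  concordant genes have their post-treatment median halved to 60 nt,
  mirroring the study shape in which three prognosis-associated genes show
  shortened tails.
* **Determinism**: one master seed, expanded with fixed offsets per stream
  (reference 101, site calls 202, counts 303, poly(A) 404), so adding a
  stream never perturbs the others and two runs are byte-identical.

What the generator does **not** emulate: alignment and basecalling error,
isoform-level expression, positional coverage bias, patient-specific
baseline methylation, overlapping genes, or sequence-driven site
placement. Passing recovery tests therefore validate the *statistics and
bookkeeping* of the pipeline, not robustness to upstream artifacts of real
nanopore data.

## Numerical and interface choices

* Coordinates: 0-based half-open everywhere internally; site TSV input
  defaults to the 1-based dialect common for per-site callers
  (`dialect = "zero-based"` flips it); BED output is 0-based half-open.
  The conversion is an involution and is tested as one.
* Zero-coverage input rows are dropped with a warning (callers emit
  uncovered positions); `modified > total`, duplicate site keys, and
  malformed rows are hard errors naming the line.
* Motifs are recomputed from the reference when a FASTA is supplied;
  disagreements with the input motif column are warned about and the
  reference wins. Sites whose window holds an N or whose center is not A
  are excluded from motif summaries only.
* The t-test for the genome-wide caller is vectorized arithmetic
  (`t = mean/(sd/sqrt(n))`, `p = 2 pt(-|t|, n-1)`) and is pinned against
  `stats::t.test` and a closed-form df=2 oracle to 1e-9 in the suite.
* The analysis path contains no random number generation; all randomness
  lives in the generator. Reports are written with stable field order so
  reruns are hash-identical.

## Problem sizes in the test suite

The suite simulates at the sizes the methods are meant for: 10,000 sites
for null calibration, 1,000 sites (x5 replicates) for effect recovery,
2,200 genes for DEG calibration, the full default study
(300 genes / ~1,400 sites / 6 samples) for end-to-end recovery. A full
synthetic study simulates in seconds and the entire pipeline runs in a few
seconds on one core, comfortably matching an interactive workflow.

## Known limitations

* The raw-P calling rule does not control FDR (see above); with sparse
  effects, use the emitted `p_adj` column.
* With three pairs the consistency filter adds nothing beyond the p-gate;
  it matters only for larger designs or one-sided tests.
* Gene-level m6A direction is a presence/absence rollup, not a
  site-weighted model; hierarchical (beta-binomial) stoichiometry models
  are out of scope.
* CPM is the only normalization offered; composition-heavy designs need
  external normalization before `call_degs`.
* Poly(A) comparisons treat reads as exchangeable within group, ignoring
  patient identity.
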