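---
title: "epicoloc: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{epicoloc: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`epicoloc` measures whether a family of query region sets — classes of
non-coding RNA loci are the motivating case — co-localizes with epigenomic
annotation tracks more or less than expected, where "expected" is defined
*within the family*. For a class of size $k$ and a track $T$:

- the observed statistic is the number $O$ of class members sharing at least
  one nucleotide with at least one interval of $T$ (member-centric: a member
  overlapping three binding sites still counts once);
- the null draws $k$ members without replacement from the pooled universe of
  all $N$ family members, of which $M$ overlap $T$; repeated sampling
  (default 1000 draws) gives the empirical null mean $E$ and variance.

Because a member's overlap status with a fixed track is itself fixed, the
null count is exactly hypergeometric with mean $kM/N$ and variance
$k\frac{M}{N}(1-\frac{M}{N})\frac{N-k}{N-1}$; the sampled estimate is kept
(rather than the closed form) because it is what generalizes when the
universe or the overlap rule changes, and the closed form then serves as an
independent check — the test suite verifies agreement at 3 standard errors
for the mean and 25% for the variance.

The pooled background is a deliberate modelling choice: sampling from the
family rather than from the genome (i) asks what distinguishes one class
from the rest of the family, and (ii) automatically matches the universe's
avoidance of low-complexity or unannotatable genomic space, which a naive
genome-wide shuffle would not. The class under test is *not* removed from
the pool; for realistic class-to-pool ratios this only dilutes effect sizes
slightly, and it keeps the null identical across classes of equal size.

Significance comes from a Pearson chi-square (df = 1, no continuity
correction) on the 2×2 table $[[O, k-O], [E, k-E]]$, with the direction of
association read from the sign of $O - E$. P-values are Benjamini–Hochberg
adjusted and transformed to signed scores $\pm\log_{10}(p_{adj})$ (negative
for depletion; 0 when $O = E$). The class × track score matrix is the
object that everything downstream consumes.

## Calibration of the chi-square construction

The 2×2 observed-vs-expected table is the classical construction used by
region-set enrichment tools, and the package keeps it as the default. It is
worth being explicit about its calibration: the independence test implicitly
assigns $O - E$ a variance of about $2kp(1-p)$ (both rows are treated as
size-$k$ samples), while the true sampling variance of $O$ is
$kp(1-p)(1-k/N)$ — smaller by a factor of roughly two. The test is therefore
*conservative*: the package's own calibration check (500 null classes of
size 200 drawn from a pool of 5,000 at overlap rate 0.3; see the test suite
and `scripts/acceptance.R`) measures a rejection rate of about 0.005 at
$\alpha = 0.05$, not the nominal 0.05. Planted effects of practical size
(×2 or ×0.5 at class size 500) are still recovered essentially always, so
the conservatism costs little power at realistic effect sizes, but border
p-values should not be read as exact tail probabilities.
`chi_square_test(kind = "gof")` offers the one-sample goodness-of-fit
variant $(O-E)^2(1/E + 1/(k-E))$, whose implicit variance $kp(1-p)$ makes it
nearly calibrated against this null; it is provided as an option rather
than the default because the 2×2 form is the construction this method
family historically used. A Yates continuity correction is likewise
available (`correct = TRUE`) and likewise off by default.

## Parameters that matter

| parameter | default | units | notes |
|---|---|---|---|
| `n_samplings` | 1000 | draws | SE of the null mean scales as $1/\sqrt{n}$; 200 is enough for the synthetic studies used in tests |
| `alpha` | 0.01 | — | presence filter and correlation track subset |
| `sd_min` | 2.0 | log10 units | drops tracks whose scores barely vary across classes |
| `bh_scope` | `per_class` | — | adjust across a class's tracks; `global` adjusts the whole matrix |
| `min_p` | 1e-300 | — | floor before $\log_{10}$, keeps underflowed p-values finite |
| `seed` | — | — | one master seed; per-(class, track) substreams are derived from it via the alphabetical ranks of the labels, so results are independent of input order and evaluation schedule |

BH scope deserves a word: adjusting per class treats each class's scan over
tracks as its own multiple-testing family, which matches how per-class
results are usually reported; the global option is stricter when classes
are compared against each other. The default is per class.

## Filtering and classification

Two column filters precede clustering, applied to tracks only (class rows
are never removed):

- **presence**: keep a track iff some class reaches $p_{adj} < \alpha$;
- **SD**: keep a track iff the sample SD (n−1 denominator) of its *signed*
  scores across classes is ≥ `sd_min` — a track uniformly enriched in every
  class carries no classifying information.

`alpha = 1` and `sd_min = 0` disable the respective rule, making the filter
the identity; the filter is idempotent and order-preserving. The SD uses
signed scores, not magnitudes: a track enriched in half the classes and
depleted in the other half is maximally informative and must survive.

Clustering uses the Chebyshev (maximum) distance and Ward agglomeration on
the fully filtered matrix, rows and columns alike. "Ward" here means the
Lance–Williams update applied to the distances as given (`hclust`'s
`ward.D`), the behaviour of classical implementations that did not
pre-square; `ward_linkage(squared = TRUE)` gives the `ward.D2` variant. The
test suite checks `ward.D` exactly against an exhaustive agglomeration that
recomputes the Ward objective from the original distance matrix at every
step.

The correlation analysis (`pearson_profiles()`) intentionally uses only the
presence filter, not the SD filter: a track consistently significant across
classes still contributes to profile similarity even though it cannot
discriminate clusters. Classes with constant profiles over the selected
tracks have undefined correlations and are flagged and excluded — zero
would fabricate dissimilarity. Ties in the best/worst-partner table break
to the earlier label. Per-class variability (`class_variability()`) is
computed on the *unfiltered* matrix, since it describes the class's whole
scan, and reports the size-vs-SD Pearson correlation with an optional
label exclusion set for classes whose extreme profiles dominate.

For class-level clustering after correlation, the package clusters
Chebyshev distances between correlation-matrix rows (the profile-of-profile
view); clustering the correlation matrix directly is possible by passing it
to `ward_linkage()` yourself.

## The synthetic generator

`generate_study()` emulates the statistical shape the analysis assumes:

- **classes**: 15 families with 52–3,024 members and right-skewed
  (log-normal, range-clamped) length distributions spanning ~15 nt to
  ~8.3 kb, per `ncrna_class_catalog()`;
- **tracks**: non-overlapping intervals hitting a target coverage within
  10% (free space distributed uniformly among gaps);
- **effects**: a sparse map (class, track) → multiplier. A member
  designated as overlapping starts inside a uniformly chosen track
  interval, guaranteeing ≥ 1 nt overlap; otherwise it is placed entirely
  within the track's complement. The planted overlap probability
  `multiplier × coverage` is therefore exact by construction, and the
  generator audits realized rates into the truth manifest.

The default genome is two synthetic chromosomes totalling 50 Mb — large
enough that a 0.35-coverage track still leaves room for complement
placement, small enough that a full 15 × 40 study generates in seconds.
`shared_state_study()` adds the correlation structure real chromatin tracks
have: two latent genome states, each track a noisy subsample of one state's
segments, each class planted to prefer one state — the configuration used
to test that the class dendrogram's first bipartition recovers the groups.

What the generator does **not** emulate: sequence content, chromosome-scale
position effects (members are placed independently), inter-track
correlation outside shared-state mode, and the heavy-tailed coverage
distribution of real ENCODE tracks. Passing tests therefore demonstrate the
statistical machinery is correct under its own assumptions, not that any
biological conclusion transfers to real data.

## Numerical and degenerate-input choices

- Coordinates: BED 0-based half-open on disk, `GRanges` 1-based closed in
  memory; overlap means ≥ 1 shared nucleotide; abutting intervals do not
  overlap. Strand is carried through I/O but ignored in all overlap tests.
  Chromosome names are exact strings — `"1"` never matches `"chr1"`; the
  input validator reports such mismatches instead of guessing.
- Duplicate intervals are legitimate (classes count members, not unique
  loci); duplicate *names* are auto-suffixed.
- Degenerate chi-square tables ($O = E$, or an expected count pinned at 0
  or $k$ with the observation equal to it) return $\chi^2 = 0$, $p = 1$,
  direction "none".
- `estimate_null()` with a single sampling reports variance 0.
- The pipeline skips clustering (with a logged notice) when the filtered
  matrix has fewer than 2 rows or columns, and skips correlation below 2
  classes or 3 significant tracks; everything upstream is still written.
- Problem sizes in the test suite are chosen to make each check sharp but
  quick: 1,000 null samplings where a closed form is compared, 500
  calibration replicates, 100 recovery replicates per direction, a full
  15 × 40 study at 200 samplings for the determinism check, and 20 seeds
  for cluster recovery.

## Known limitations

- The amount of overlap is ignored — a 1-nt graze and full containment
  count the same. This is the method's historical definition; fractional
  overlap would need a different null.
- The chi-square construction is conservative against the sampling null
  (see above); borderline adjusted p-values are best treated as ordering,
  not calibrated probabilities.
- The pooled background means conclusions are relative to the family
  universe; classes absent from the pool change every other class's null.
- Very small classes (tens of members) rarely reach significance at
  `alpha = 0.01` after correction — an intrinsic power limit, not a bug.
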