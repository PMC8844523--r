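---
title: "Models and methods behind kinfolk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind kinfolk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinfolk)
```

`kinfolk` post-processes SNP-based relatedness estimates: it computes
expected kinship from pedigrees, bins kinship coefficients into relationship
degrees, scores degree classifiers, and converts shared IBD segments into
kinship. This vignette explains the models behind each step, the choices
that were genuinely open, and what the synthetic data can and cannot tell
you about real data.

## Pedigree kinship

The kinship coefficient φ(i, j) is the probability that an allele sampled
at random from individual i and one sampled from j at the same autosomal
locus are identical by descent. `kinship_matrix()` implements the classical
founder recursion over a parents-first ordering: founders are mutually
unrelated with self-kinship 1/2, a non-founder's self-kinship is
1/2 + φ(dad, mom)/2 (inbreeding raises the diagonal), and its kinship with
any previously processed individual averages its parents' values. Because
`fam2ped()` topologically sorts members (Kahn's algorithm, which doubles as
the cycle check), "previously processed" always covers every
non-descendant, which is what the recursion requires. Looped (inbred)
pedigrees need no special casing.

Validation choices in `fam2ped()` follow what the recursion needs, not what
`.fam` files happen to contain. Parents must come in pairs (the recursion
averages over two parents), so single-parent rows are rejected unless
`fix_parents = TRUE` pads a deterministic synthetic founder
(`"<child>_padded"`); silently inventing ancestry seemed worse than an
explicit, named repair. Only the literal token `"0"` (or an empty field)
means "no parent" — any other string is taken to be an id, because `.fam`
files in the wild use arbitrary id schemes. Sex codes outside {1, 2} are
accepted as unknown and exempt from the father-not-female /
mother-not-male consistency check.

Two independent oracles check the recursion in the test suite: exhaustive
enumeration of all 4^(non-founders) transmission patterns on small
pedigrees (exact, including an inbred loop with self-kinship 5/8), and the
single-locus Monte-Carlo gene-dropper `drop_alleles()` (50,000 transmission
replicates; agreement required within three standard errors for every pair
of the reference three-generation family). Neither shares code with the
recursion.

## Degree inference

`dibble()` tabulates, for degrees 0..`max_degree`, the expected kinship
2^−(d+1) and the inference interval [2^−(d+3/2), 2^−(d+1/2)) of
Manichaikul et al. — geometric midpoints between adjacent expected values,
so l·u = k² row by row and adjacent intervals tile the line exactly. Two
deliberate edge conventions:

* the degree-0 interval is closed at an upper cap of 1 rather than 1/2,
  because noisy estimators can legitimately exceed the theoretical maximum;
* the unrelated band stores l = −1 so that negative kinship estimates
  (routine from moment estimators on distant pairs) classify as unrelated
  instead of erroring.

The interior closure convention — lower-inclusive, upper-exclusive — is not
something the inference-range construction itself pins down; we fixed [l, u)
so the bands partition (−1, 1] with no gaps or overlaps, and document it
here because a kinship estimate landing exactly on a bound (possible with
the dyadic values produced by pedigrees) must classify deterministically.
`kin2degree()` is a vectorized `findInterval()` over the shared bounds, and
the tests compare it against a naive linear scan of the `dibble()` rows.

Intervals narrow geometrically with degree: beyond roughly the 8th degree
they are thinner than typical estimator noise, so `dibble()` warns at
`max_degree >= 10` and refuses `>= 12`.

## Benchmarking degree classification

`confusion_matrix()` reports four components: an accuracy block, per-class
statistics with a macro-average row, the predicted × target contingency
table, and the reciprocal RMSE. The accuracy interval is an exact
Clopper–Pearson 95% interval and the p-value is a one-sided exact binomial
test of the observed correct-call count against the no-information rate
(the largest target-class prevalence) — the same conventions as
`caret::confusionMatrix()`, against which the test suite cross-checks every
shared statistic. The label universe is the union of target and predicted
labels, ordered numerically with `"unrelated"` last; a label seen only in
predictions contributes a zero-count target column, and a class absent from
both margins is dropped from the per-class table.

Plain accuracy treats calling a parent "second degree" and calling a 5th
degree cousin "6th degree" as equal mistakes. The reciprocal RMSE

$$\mathrm{R\text{-}RMSE} = \sqrt{\frac{1}{n}\sum_{i=1}^{n}
\left(\frac{1}{T_i + 0.5} - \frac{1}{P_i + 0.5}\right)^2}$$

maps degrees through d ↦ 1/(d + 0.5) before the squared error, so
close-relative confusions dominate; the +0.5 keeps degree 0 finite.
`"unrelated"` is scored as `max_degree + 1` (one step past the resolved
range), which is the convention under which the statistic on the reference
288-pair confusion table reproduces its reference value (0.4665971) and
keeps the penalty ladder strictly decreasing in degree. The denominator is
the number of pairs, inside the square root.

## IBD segments to kinship

`ibd2kin()` estimates kinship as the summed genetic length shared IBD at
haplotype-pair resolution divided by 4 × the total map length. The constant
is forced by two identities: an individual sharing one entire haplotype
with another (parent–offspring) must score 1/4, and sharing both
haplotype pairs everywhere (self, identical twins) must score 1/2. This is
also why ped-sim `IBD2` segments are duplicated on read — they assert
sharing on both haplotype pairs — and why overlapping records per pair are
legal rather than merged.

Segment genetic lengths are recomputed from the supplied map
(`interpolate_cm(end) − interpolate_cm(start)`) rather than trusted from
the file. The estimate is only meaningful when the same map underlies
segment inference and kinship conversion; recomputation makes that
dependence explicit, and a recomputed length differing from the reported
one by more than 1 cM triggers a warning (differences below that are
ordinary map-resolution noise). Interpolation is linear between map points
and clamps (rather than extrapolates) beyond the ends, so off-map
coordinates cannot produce negative or runaway lengths. Chromosome labels
are compared after stripping a `chr` prefix. Pairs with no segments are
absent from the output rather than reported as zero: absence of evidence of
sharing is left distinguishable from evidence of near-zero sharing.

## The synthetic generator, and what passing tests mean

`make_families()` reproduces a fixed three-generation layout (founder
couple; two married children; one grandchild per branch — 8 members, 36
pairs, kinship values {0.5, 0.25, 0.125, 0.0625, 0}) because that structure
exercises every relationship class the default degree resolution
distinguishes; the default of 8 families matches the 288-pair benchmark
scale used throughout the examples. It is deterministic by construction —
the family structure is a study condition, not a random draw.

`gene_drop()` transmits founder haplotypes with crossovers placed as a
Poisson process on the genetic scale (rate 1 per Morgan), no interference,
a single sex-averaged map, and no genotyping error or phase noise. That is
sufficient for its purpose — an expectation-level oracle whose mean sharing
matches pedigree kinship — but it is deliberately simpler than real data:
real IBD detection contends with crossover interference, sex-specific maps,
segment-detection boundary error, and false negative short segments. A
passing Monte-Carlo test therefore validates the *conversion arithmetic*
and the *expectations*, not the robustness of any upstream IBD caller.
Defaults (2 chromosomes × 100 cM × 10⁸ bp) are chosen so a chromosome
averages one crossover per meiosis; tests use 1–2 chromosomes and
200–1,000 replicates, which keeps the Monte-Carlo standard error small
enough for three-standard-error acceptance bands while running in seconds.

`flip_labels()` degrades labels by replacing each with probability
`flip_rate` (default 0.2) by a uniform draw from the distinct observed
labels; the draw may repeat the original, so the realized change rate is
`flip_rate · (1 − 1/n_distinct)`. Randomized utilities take an explicit
`seed` and restore the caller's RNG state, so fixture generation never
perturbs a surrounding simulation.

## Numerical conventions

Kinship values from pedigrees are exact dyadic rationals represented in
double precision; tests compare them exactly or at 10⁻¹² where an oracle
is itself floating-point. Pair tables are canonicalized by lexicographic id
order within a pair and sorted by (fid, id1, id2); row order is
presentation, not semantics. Physical coordinates are treated as 1-based
inclusive; genetic length uses endpoint interpolation differences, so
base-level off-by-one effects are orders of magnitude below cM resolution.

## Known limitations

* Kinship only: the k0/k1/k2 Cotterman coefficients, X-chromosome kinship,
  and likelihood-based degree inference are out of scope.
* No pedigree drawing.
* `ibd2kin()` does not merge or gap-stitch segments and applies no
  LOD/length filtering; it scores exactly the segments it is given.
* The gene-dropper is not a replacement for ped-sim: no interference, no
  sex-specific maps, no error models.
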