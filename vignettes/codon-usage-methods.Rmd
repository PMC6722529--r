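---
title: "Codon usage bias: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon usage bias: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonbias)
```

## The problem

Synonymous codons are not used uniformly. Two classes of explanation are
standard: directional mutation pressure, which pushes base composition —
most visibly at third codon positions, where most changes are synonymous
— toward a mutational equilibrium; and natural selection, notably
translational selection toward the tRNA pool of the expressing cell (for
a virus, its host). `codonbias` implements the statistics conventionally
used to measure bias and attribute it between these forces, plus a
generative model to validate them.

All statistics work on the **59-codon universe**: the 61 sense codons
minus AUG (Met) and UGG (Trp), which are the sole codons of their amino
acids and therefore carry no information about synonymous choice; stop
codons are never counted. Sequences are stored in the DNA alphabet and
printed as RNA, the convention of published codon-usage tables.

## The statistics

**RSCU.** For codon *i* of amino acid *j* with counts *g~ij~* and family
size *n~j~*, RSCU = *g~ij~* / mean(*g~·j~*), the ratio of observed to
expected count under equal synonymous usage. 1 means no bias; the
conventional calls are overrepresented above 1.6 and underrepresented
below 0.6 (both configurable). A family never observed in a sequence is
**undefined** (NA), not zero: imputing 0 would claim maximal avoidance
from absence of evidence. Group-level RSCU defaults to the mean of
per-sequence vectors over the sequences where the family is defined —
matching how group means are produced from per-strain tables — with
RSCU-of-pooled-counts as an explicit alternative (`mode = "pooled"`);
the two differ whenever sequence lengths or compositions are unbalanced.
The most-used codon per family is marked; exact ties are broken
lexicographically and flagged.

**ENC.** Wright's effective number of codons summarises bias without
reference to composition: per family, the homozygosity estimator
F = (nS − 1)/(n − 1) with S = Σ(nᵢ/n)², averaged within degeneracy
classes (9 twofold families, Ile alone threefold, 5 fourfold, 3
sixfold), then ENC = 2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ + 3/F̄₆. The range is 20
(one codon per family) to 61 (uniform usage); values at or below 35 are
conventionally read as significant bias. Numerical choices:

- families with n < 2 are undefined and skipped; F ≤ 0 (possible when
  nS = 1) is excluded from the class mean, with diagnostics;
- a missing threefold class (no Ile observed) is imputed as
  F̄₃ = (F̄₂ + F̄₄)/2, Wright's interpolation between the neighbouring
  classes; real genes essentially always contain Ile, so this is a
  safeguard for artificial inputs;
- a missing sixfold class has no established correction; we impute
  F̄₆ = F̄₄ (the nearest class) and mark the result unusable rather than
  fail, since the situation only arises for pathological inputs;
- a missing twofold or fourfold class is an error ("sequence too short");
- sampling noise can push ENC slightly above 61; such values are clamped
  to 61 and flagged, with the raw value retained.

**ENC-plot.** The null curve ENC\* = 2 + s + 29/(s² + (1 − s)²), with s
the synonymous third-position G+C fraction (GC3s), gives the ENC a gene
would show if composition alone set its bias. Genes below the curve are
read as additionally constrained by selection. GC3s here is computed on
the same 59-codon subset as everywhere else, so the plot is internally
consistent.

**PR2.** Within fourfold-degenerate families, pure mutation pressure
with no strand asymmetry predicts A3 = U3 and G3 = C3. The plot of
A3/(A3+U3) against G3/(G3+C3) therefore centres at (0.5, 0.5). The
default uses only the strictly fourfold amino acids (Ala, Gly, Pro, Thr,
Val); whether the fourfold boxes of the sixfold families (CUN, UCN, CGN)
belong in a "four-codon family" analysis is genuinely ambiguous in the
literature, so both modes are provided (`mode = "include6fold"`).

**Neutrality regression.** GC12 (mean of GC1s and GC2s) is regressed on
GC3 by ordinary least squares across genes. Under mutation pressure
alone all positions drift together and the slope is 1; selection on
amino-acid content (positions 1–2) flattens it. We report the slope as
mutation share ×100 and define the selection share as 100 − mutation
share, so the split always sums to 100.

**CAI.** Relative adaptedness w of a codon is its host-table frequency
divided by the maximum in its family; CAI is the count-weighted
geometric mean of w, in (0, 1], with 1 meaning every codon is
host-preferred. Met/Trp are excluded (w ≡ 1, no information).

**RCDI.** The usage-weighted mean ratio of the query's within-family
relative frequencies to the host's: 1 exactly at host-matched usage,
larger otherwise (a Cauchy–Schwarz consequence, which the tests exercise).
Note that RCDI penalises *any* mismatch — a gene using only the host's
preferred codons is over-optimised relative to the host's own mixture
and scores above 1.

**SiD.** R(A,B) is the cosine similarity of the virus's and host's
59-dimensional RSCU vectors (undefined entries dropped pairwise). The
transform to a distance is written ambiguously in parts of the
literature ("1 − R/2" vs "(1 − R)/2"); we default to SiD = (1 − R)/2,
which is 0 for identical profiles and bounded by 0.5 for non-negative
vectors, and expose SiD = 1 − R/2 behind
`convention = "one-minus-half"` rather than guess further.

**Host tables.** Kazusa-style text (`GCU 17.6 ( 12345)`) or a plain
codon/count TSV. All derived quantities are scale-invariant in the
table. If any sense codon has count 0, a pseudocount of 0.5 is added to
every count before normalisation (the Sharp–Li-style 0.5 rule), keeping
log w and frequency ratios finite; the table is flagged and RCDI warns
when it is used.

**PCA.** Sequences are points in the 59-dimensional RSCU space; the
matrix is column-centred but not scaled (RSCU values are already on a
common scale) and decomposed by singular values. Undefined entries are
imputed with the column mean, which makes them exactly inert after
centring. Axis signs are fixed deterministically — the largest-|loading|
coefficient is made positive, with near-ties (within 1e-8) resolved to
the smallest index — so score tables reproduce bit-for-bit regardless of
input order. A zero-variance input is reported as degenerate rather
than decomposed.

**Correlations.** Spearman rho with mid-rank ties; p-values from the t
approximation on n − 2 degrees of freedom, exact (via `cor.test`) for
n ≤ 10 without ties; stars ** for p < 0.01 and * for 0.01 ≤ p < 0.05.
Constant columns yield a flagged NA instead of an arbitrary rho.

## Input handling

CDS records must have length divisible by 3 and no internal stop codon
(fatal per record); a terminal stop is stripped and remembered. Codons
containing ambiguity codes are dropped by default (`ambiguity =
"drop"`), since rejecting a whole otherwise-clean record discards
analysable signal; `"reject"` is available when stricter curation is
wanted. Invalid records are skipped with a warning by default or abort
the read (`on_invalid = "abort"`).

Reported percentages are on the 0–100 scale. Group summaries default to
the population SD (divisor n), configurable to sample SD, since
conventions differ between the tools this package mirrors.

One range note: GRAVY is sometimes described as ranging −2 to 2; that
describes typical proteins, not the scale. The Kyte–Doolittle
per-residue values span ±4.5 and we do not clamp.

## The synthetic generator

`generator_spec()`/`generate_cds()` produce CDS by a two-route mixture.
Per position: draw an amino acid from a profile (default uniform over
the 20); with probability `w_sel` emit the host table's preferred codon
(translational selection); otherwise draw the third-position nucleotide
from the mutational distribution π (renormalised over the third
positions the family offers) and choose uniformly among synonyms with
that third position — the one place first/second-position composition is
only indirectly controlled. Optional substitution noise replaces codons
with uniform random sense codons. Seeds are mandatory.

What it emulates: mutational third-position bias, host-directed
selection of tunable strength, labelled groups — enough to make ENC,
RSCU, PR2, CAI/RCDI/SiD and the neutrality slope respond the way the
theory predicts. What it does not emulate: phylogenetic correlation
between sequences, indels/recombination, codon-pair or dinucleotide
effects, and realistic amino-acid composition drift. Passing
parameter-recovery tests on this generator therefore validates the
estimators' mechanics, not their behaviour on real, phylogenetically
structured data.

Fixture defaults are frozen to the two compositional regimes the
analysis is designed around: a GC-rich gene class
(π₃ = A .11, C .30, G .44, U .15, realised mean GC ≈ 53.8%) and an
AU-rich class (π₃ = A .26, C .20, G .24, U .30, realised mean
AU ≈ 54.9%), 30 sequences × 300 codons each, three host labels.

**Neutrality null.** For slope recovery, the generator above is
deliberately *not* used: with a fixed amino-acid profile, positions 1–2
cannot respond to mutation pressure and the GC12-on-GC3 slope would be
attenuated by construction, not by selection. `neutrality_series()`
instead draws each codon with probability proportional to the product of
its three per-position nucleotide probabilities over the 61 sense
codons, so amino-acid composition itself covaries with the mutational
distribution. Even so the slope's ceiling is about 0.97, not 1.00:
excluding the three stop codons distorts the sense-codon marginals
slightly. Two problem-size choices matter and are set from a variance
argument, not tuned: the mutational GC level spans 0.25–0.75 (variance
≈ 0.021), and validation genes are long (8000 codons in the acceptance
suite; 2000 by default) because per-gene GC3 is measured with binomial
noise ≈ 0.25/L which otherwise attenuates an errors-in-variables
regression — at L = 8000 the attenuation factor is above 0.99, leaving
the structural ceiling as the dominant gap.

**Selection response.** The monotonicity checks (ENC and RCDI decrease,
CAI increases across w_sel ∈ {0, 0.25, 0.5, 0.75, 1}, 100 replicates of
300 codons per level) use a near-deterministic host table (counts 1000
vs 1). This is not incidental: against a weakly biased host, RCDI is
*not* monotone in w_sel — the pure-preferred limit overshoots the host's
mixed usage and RCDI rises again. Monotonicity toward RCDI = 1 is a
property of selection toward a strongly biased target, and the test
encodes exactly that regime.

## Pipeline

`run_codon_pipeline()` wires the stages together and emits one TSV per
stage plus a manifest and a run log; it adds no computation of its own,
so every number in the tables is reproducible by calling the module
functions directly (a property the tests assert). Numbers are printed at
4 decimals next to full-precision `_raw` columns. Outputs contain no
timestamps and are byte-identical under a fixed config and seed. Stage
failures abort with the stage name in the error.

## Known limitations

- Only the standard genetic code is supported.
- ENC is Wright's original estimator; background-composition-corrected
  variants (ENC′) are out of scope.
- The neutrality regression is OLS; errors-in-variables fits are not
  provided, so slopes from short genes are attenuated (see above).
- Group RSCU means exclude undefined families rather than modelling
  them; for very short sequences this can leave a family with few
  contributing sequences.
- Real host codon-usage tables are user-supplied; the shipped tables are
  synthetic mocks for testing and examples.
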