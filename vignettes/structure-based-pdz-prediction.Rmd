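---
title: "Methods: structure-based prediction of PDZ domain-peptide interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-based prediction of PDZ domain-peptide interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pdzpred)
```

## The prediction problem

PDZ domains recognize the extreme C-termini of partner proteins. The
binding event is localized: a small number of domain residues line the
peptide-binding groove, and their geometry, hydrogen-bonding pattern and
surface physicochemistry determine which pentapeptides are accepted.
`pdzpred` casts the problem as binary classification of
(domain, C-terminal pentapeptide) pairs. The domain enters through a
structure-derived feature vector; the peptide through its sequence; the
classifier is a kernel SVM over the concatenated pair vector. The model
therefore generalizes across domains to the extent that structural
features, not domain identity, carry the signal — which is exactly what
the leave-domain and similarity-filtered cross-validation schemes
measure.

## Core binding site

The binding site is an ordered list of alignment columns (default length
ten). `derive_core_positions()` reproduces the defining procedure: a
column is a core position when, in at least a majority of the supplied
domain-peptide complexes, a heavy atom of the mapped domain residue lies
strictly closer than 4.5 Å to a heavy atom of the peptide chain. Two
conventions are deliberate, since the defining text fixes neither:
contacts use heavy atoms only, and the cutoff is a strict `<`; the
multi-complex aggregation defaults to a majority (`min_structures`) and
is configurable, so an intersection or single-complex reading is
expressible. Derived sites are plain configuration afterwards
(`BindingSiteDefinition`), and a domain whose alignment has a gap at any
site column is refused as unsupported rather than silently padded.

## Structure features and their stand-ins

Four feature blocks are computed per site position, concatenated in a
fixed order (50 + 10 + 90 + 90 = 240 values):

* **Binary structural descriptors (5 bits/position).** Solvent
  accessible (relative accessibility ≥ 7%, the JOY convention);
  side chain H-bonded to a main-chain amide; to a main-chain carbonyl;
  to another side chain; positive backbone φ. The original pipeline
  delegated these to the JOY server, whose precise H-bond geometry is
  unpublished; the package uses standard geometric criteria instead:
  donor-acceptor distance ≤ 3.5 Å and, because explicit hydrogens are
  usually absent, an antecedent–donor–acceptor angle ≥ 90°, with
  donor/acceptor atoms from fixed per-residue tables. Residues with
  undefined φ (chain start, missing backbone atoms) encode the
  positive-φ bit as 0 and are reported as undefined, never as 0°.
* **Accessible area (1 value/position).** Shrake–Rupley with probe
  1.4 Å, 960 deterministic golden-spiral sphere points per atom, and
  Bondi van der Waals radii (carbon 1.70 Å — chosen so the isolated-atom
  closed form 4π(r+p)² holds exactly as documented). Relative
  accessibility uses Gly-X-Gly theoretical maxima and is deliberately
  uncapped.
* **Surface electrostatics and hydrophobicity (9 values each/position).**
  The original features came from VASCo, whose potential model and
  point-selection rule are not published. The package's documented
  stand-ins: a Coulomb potential with distance-dependent dielectric
  ε = 4r evaluated at exposed Shrake–Rupley points, with formal charges
  from a bundled table (split over the canonical charged atoms; if a
  charged residue lacks them — e.g. reduced side chains — the charge
  sits on the side-chain atom farthest from CA); and the Kyte–Doolittle
  value of the residue owning each surface point. The nine samples per
  position are the nine exposed points nearest the residue's side-chain
  centroid, ordered by distance — fully deterministic.

Because the Shrake–Rupley point grid is fixed in space, surface features
would weakly depend on the input frame. `encode_domain()` therefore
first canonicalizes the structure — centering on the atom centroid and
rotating into the principal-axes frame with skewness-fixed signs — which
makes the full 240-vector invariant under rigid motion of the input to
floating-point precision. Degenerate (near-symmetric) atom sets would
make the frame arbitrary but still deterministic for a given input.

Peptides are encoded as 5 × 20 sparse indicator bits, alphabet ordered
alphabetically by one-letter code (A, C, D, …, Y), positions −4…0 with 0
the C-terminus.

Features are min-max scaled to [0, 1] with parameters fitted on the
training vectors only; constant dimensions map to 0, and out-of-range
test values are *not* clamped (a value of 20 after fitting on {0, 10}
scales to 2.0), so distribution shift remains visible to the classifier
and to the diagnostic warning in `predict()`.

## Classifier

The SVM solves the usual soft-margin dual with per-class box
constraints, weighted costs tied by C⁺ = (n⁺/n⁻)·C⁻ exactly as the
method prints them. Note this *down-weights* errors on the minority
class whenever positives are rarer — the opposite of the common
balancing heuristic; `invert_class_weights = TRUE` provides the
conventional n⁻/n⁺ form, but the printed rule is the default on
fidelity grounds. The dual is solved by libsvm through e1071; the
package stores support vectors, oriented dual coefficients αᵢyᵢ, and
bias, and `predict()` evaluates its own kernel expansion
Σᵢ αᵢyᵢK(xᵢ,x) + b, so the solver's decision output remains an
independent cross-check in the test suite rather than the prediction
path, and persisted models (portable JSON) predict identically without
the solver object. The decision rule is sgn with sgn(0) = +1.

Grid search maximizes mean inner-CV ROC AUC over γ ∈ {2⁻¹⁵ … 2³} and
C⁻ ∈ {2⁻⁵ … 2¹⁵} (5 inner folds, ties to smaller C⁻ then smaller γ);
the fold count and the AUC objective are documented choices where the
method states only "grid search". Package defaults outside grid search
are γ = 1/340 (the libsvm 1/dim convention) and C⁻ = 1.

## Training data construction

PWMs over the five peptide positions use
(count + pseudocount)/(n + 20·pseudocount) per cell; scores are log₂
odds against a uniform 0.05 background (both the background table and
the pseudocount are arguments). Artificial negatives are sampled
uniformly (seeded) from the bottom quantile of PWM scores over a
C-terminal peptide pool — the defining protocol says only "low
scoring", so the quantile (default 0.25) is exposed. A peptide is
*genomic* when its last four residues terminate some proteome sequence;
training domains need at least four genomic positives and at least one
negative.

The semi-supervised expansion loop scans the proteome tails with the
current model; every domain exceeding `hit_threshold` predicted hits
contributes up to `per_domain_cap` of its top-decision-value hits (never
known positives) as negatives with provenance `svm_negative`, and the
model is retrained; the loop stops at convergence or `max_rounds`.
The published account leaves the loop's internals to supplementary
material, so the defaults encode its printed traces: caps near ten
negatives per flagged domain and a 1000-hit over-prediction threshold at
proteome scale. On the package's toy proteomes (hundreds of tails rather
than tens of thousands) proportionally larger caps and smaller
thresholds exercise the same mechanics; the invariants — experimental
records are never removed, no peptide is both +1 and −1 for a domain,
added records carry the svm_negative provenance — hold at any scale.

## Evaluation

`run_cv()` implements four schemes: ten-fold partition of interactions;
and holdouts of 12% of domains, 8% of peptides, or both, with *all*
their interactions, repeated ten times by default. Scalers and any
hyperparameter search are refit inside each training fold only. Folds
whose test half contains a single class are skipped and recorded as
missing, never as zero. Sensitivity, specificity and precision follow
the printed formulas with undefined ratios flagged `NA`. ROC AUC is the
trapezoid over the tie-grouped ROC curve (exactly the tie-corrected
Mann–Whitney statistic, which the tests assert to 1e−9); PR AUC is the
trapezoid over tie-grouped (recall, precision) points anchored at
recall 0 — for random scores it equals the positive fraction.

The similarity-filtered variant retains a training domain only when its
binding-site sequence identity to every test domain is below a
threshold, caps training sets at 500 interactions by seeded subsampling
(the cap's sampling rule being another documented choice), and runs ten
holdouts × ten repeats per threshold. Fraction identity over the ten
site positions is the default similarity; the encoding-space normalized
dot product is the obvious plug-in alternative and the API accepts any
per-pair function of the stored site sequences. A threshold above 1
filters nothing and reproduces the plain leave-domain composition for
the same seed — a contract the tests pin down.

## Proteome scanning and specificity comparison

`scan_proteome()` predicts each (domain, unique pentapeptide) pair once
and expands hits back to every protein sharing that C-terminus;
per-domain unique-peptide hit counts are the over-prediction diagnostic.
Predicted specificities are PWMs over positions −4…0 built from at least
four unique hit peptides (the logo-construction convention). PWM
similarity is 1 − D/D_max with D the Euclidean distance between
probability matrices and D_max = √(2·columns), the largest distance two
column-stochastic matrices of that shape can achieve; it is 1 exactly at
equality and 0 for disjoint one-hot matrices. The exact normalization
used in the original supplementary material is unavailable, so the
package relies on these fixed points rather than on any printed
similarity value; whether published similarities used probability or
information-content matrices is likewise flagged as unknowable from the
main text. Logos use Schneider–Stephens information heights and are a
reporting convenience only.

## The synthetic study

`fixture_spec()` fixes the study conditions; every fixture is a pure
function of the seed. Defaults: 20 domains in 2 archetypes, 30 positives
and 60 negatives per domain (the 1:2 class ratio of the real training
compendium), a 400-sequence proteome with 10% planted binder tails,
helix conformation (φ = −57°, ψ = −47°), planted PWMs putting 0.7 on
each consensus letter, and ±0.15 Å coordinate jitter.

Domains are idealized backbones built by internal-coordinate (NeRF)
placement with single pseudo-atom side chains at Cβ. A six-residue
extended peptide chain is placed 13.5 Å from the binding-site centroid
along the least-variance principal axis, and each site residue receives
an extra side-chain pseudo-atom 4.0 Å from its nearest peptide atom —
so the planted ten positions, and only those, satisfy the < 4.5 Å
contact rule even under jitter (the offset leaves non-site atoms ≥ ~5 Å
away). Archetypes differ in site-residue identity (basic/polar versus
acidic/hydrophobic), which the electrostatic and hydrophobicity blocks
pick up, and in their planted peptide PWM, so the interaction classes
are learnable from the pair encoding.

What the fixtures deliberately do **not** emulate: real PDZ folds,
rotamers, NMR ensembles, homology-model error, non-canonical binding
modes, or proteome-scale tail distributions. Passing the end-to-end
gates therefore demonstrates that the pipeline's contracts and learning
machinery are correct — not that the biophysical stand-ins reproduce
published accuracies on real data, which would require the original
phage-display/microarray interactions and structure set.

## Numerical choices and problem sizes

Sphere points 960/atom (the 10× oracle uses 9600); SASA tolerance
asserted at 5% per residue against that oracle; dual feasibility at
1e−6; kernel-expansion equality at 1e−6 against the solver and 1e−9
against a brute-force double loop; dihedrals at 1e−9° against an
independent four-point formula. Ties in decision values are grouped in
both AUC curves; grid-search ties resolve to the smaller C⁻ then
smaller γ. The shipped evaluation sizes — 1800 interactions for CV,
~360 unique tails for scanning, 200 sampled hits for PWM recovery —
were chosen as the smallest sizes at which the planted effects are
comfortably resolved, and run in a few minutes on one core.

## Known limitations

Electrostatics and hydrophobicity are desk-scale stand-ins, pluggable
but not validated against Poisson–Boltzmann surfaces; H-bond criteria
ignore explicit hydrogens; the canonical frame is arbitrary for exactly
symmetric atom sets; `filter_training_domains` treats the proteome tail
set as ground truth for genomicity; and the semi-supervised loop's
correspondence to the original supplementary procedure is an
interpretation, parameterized so that both hits-as-negatives and
non-hits readings are expressible.
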