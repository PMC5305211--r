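---
title: "Mapping photo-crosslinks onto structure ensembles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping photo-crosslinks onto structure ensembles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xlmap)
```

## The problem

ISWI-family chromatin remodelers are regulated by an autoinhibitory
N-terminal region (NTR) and activated by the histone H4 N-terminal tail.
Where these elements dock on the ATPase module can be mapped without a
crystal structure by zero-length photo-crosslinking: a benzophenone group —
introduced either genetically as *p*-benzoyl-phenylalanine (Bpa, written
`B`) or chemically as a 4-maleimidobenzophenone adduct on an engineered
cysteine (written `X`) — inserts into a nearby C–H bond upon 365 nm
irradiation. Because the insertion neither adds nor removes atoms, a
crosslinked tryptic peptide pair weighs exactly the sum of its two
peptides, which makes identification by accurate precursor mass unusually
clean. The identified residue pairs then become upper-bound distance
restraints that select, from an ensemble of docked peptide–protein models,
the family of poses consistent with the chemistry, and the retained family
is summarized as a per-residue contact-probability surface. Enzyme assays
(NADH-coupled ATP hydrolysis, restriction-enzyme accessibility remodeling
time courses) quantify the functional consequences.

`xlmap` implements this chain as a tested R package: mass calculus,
crosslink search, restraint filtering, contact surfaces, and the kinetic
reductions, plus seeded simulators for every input so the whole pipeline is
verifiable without instrument data.

## Mass calculus

Monoisotopic masses are computed from elemental compositions using standard
IUPAC residue formulas; a second, independent code path sums per-residue
monoisotopic masses, and the two are tested against each other. Electron
mass is ignored throughout; for neutral masses of 1–3.5 kDa this biases
relative errors by well under 0.5 ppm, below the instrument windows used.

Two photo-reactive residue letters extend the alphabet:

* `B` (Bpa) = Phe + C7H4O (+104.0262 Da over Phe),
* `X` (benzophenone-labeled Cys) = Cys + C17H11NO3 (+277.0739 Da over Cys).

Two positioned modifications are supported: methionine oxidation
(+15.9949 Da, variable, at most one per peptide by default) and
carbamidomethyl cysteine (+57.0215 Da). Carbamidomethylation is applied as
a **fixed** modification on every unlabeled cysteine: the bundled reference
masses for crosslinks involving `VLDILEDYCMWR` reconcile within a few ppm
only with the alkylated cysteine, the expected state after in-gel tryptic
digestion, so the package makes that the default rather than an option the
user must remember. Similarly, two bundled entries (`XL15`, `XL13c`) only
reconcile with one unannotated methionine oxidation; the fixture marks
these `inferred_ox` and the search treats oxidation as a variable
modification, which reproduces both masses.

The ppm error convention is `(observed − theoretical) / theoretical`.
The printed signs in the bundled tables are not consistent with any single
convention (some entries are printed negative where the observed mass
exceeds the recomputed theoretical mass, others the opposite), so tests
assert magnitudes, which reproduce to about 0.1 ppm.

Isotope patterns are computed by exact polynomial convolution of
per-element isotopologue distributions on a neutron-offset grid — no
averagine approximation, since compositions are fully known. Peaks are
reported at `mono + k × 1.00335` Da and renormalized to sum to one over the
returned peaks; truncation is monotone (adding peaks rescales but never
reorders earlier ones).

## Crosslink search

Digestion follows the tryptic rule (cleave C-terminal of K/R, suppressed
before P) with up to 2 missed cleavages and peptide lengths 2–30 by
default. Two missed cleavages are needed because published bait peptides
such as `LDGQTPBEDRNR` carry one. The digest is validated against an
exhaustive substring oracle.

Candidates are Cartesian pairs of bait peptides carrying exactly one
photo-residue with prey peptides, expanded over oxidation variants. MS1
matching uses a ±10 ppm window (the survey-scan accuracy of the original
acquisitions), MS2 fragment matching ±15 ppm; fragment charges 1 to
(precursor − 1) are considered and neutral losses are ignored. Any b/y
fragment containing the linked residue carries the entire partner peptide
as a rigid added mass. Because the link site on the target chain is unknown
a priori, fragments are generated under every site hypothesis; a site is
*consistent* when it explains every peak that any hypothesis explains, and
the reported localization is the smallest contiguous interval of
consistent sites — the full peptide when nothing discriminates, matching
the "sites not distinguishable" annotations in the reference tables.

UV dependence is quantified as summed +UV intensity over summed −UV
intensity for features within the MS1 window of the species mass, with the
−UV signal floored at 1% of +UV to avoid division by zero; ≥5-fold flags a
species UV-dependent. The published confidence ratings were assigned by
manual expert validation; `tier_matches()` codifies them as a deterministic
rubric (high: ≥3 matched fragments on *each* chain, UV-dependent, |MS1
error| ≤ 5 ppm; medium: ≥3 fragments on at least one chain; low:
otherwise), with every threshold exposed in the run configuration. Error
control uses a seeded Fisher–Yates-shuffled prey sequence as decoy, since
no FDR procedure applies at this scale.

## Restraints, filtering and contact surfaces

Each localized crosslink becomes one upper-bound distance restraint,
default 20 Å between Cα atoms. The original workflow used the bound inside
a docking engine as an upper harmonic potential; after refinement, models
were *filtered* for restraint satisfaction, and it is that post-hoc filter
this package implements — a hard distance test, which is what "still
satisfies the restraints" requires. The atom selection is configurable
(Cα default; the paper names no atom). A localization range (e.g. 519–522)
yields an ambiguous restraint satisfied when **any** residue of the range
is within the bound, because the chemistry marks exactly one unknown
residue in the range. Matches collapsing to the same residue linkage are
deduplicated; the five bundled high-reliability H4-tail crosslinks collapse
to three unique linkages, reproducing the published count.

`filter_ensemble()` retains exactly the models satisfying every restraint;
it is idempotent, monotone in the bound and antitone in the restraint set,
all property-tested. The published count of 383 surviving models is a
consequence of the original stochastic docking run and is not
reproducible from the filtering semantics alone; it is therefore not a
target here.

Contacts are defined as minimum heavy-atom distance ≤ 5 Å (the published
color scales define no cutoff; 5 Å is the common heavy-atom contact
convention). `contact_surface()` reports both the pairwise probability
(fraction of models with the contact) and the per-receptor-residue marginal
(fraction of models contacting *any* peptide residue), since the published
surfaces do not say which was drawn; the marginal, scaled 0–100, is also
written into PDB B-factors for viewing.

## Kinetics

ATP hydrolysis is monitored through NADH-coupled absorbance at 340 nm:
turnover = −slope / (ε · l · [E]) with ε = 6220 M⁻¹cm⁻¹ and l = 1 cm
(standard values for NADH; the assay is cited by reference in the source
study). The slope is taken over the longest window with linear-fit
R² ≥ 0.995 covering at least 30% of the points, earliest such window on
ties. Remodeling time courses are fit to
`y(t) = y∞ + (y0 − y∞)·exp(−k·t)` by Levenberg–Marquardt with a
deterministic initialization (`y∞` from the final 10% of points, `k` from
log-linear regression over the clearly decaying points, i.e. those more
than 2% of the amplitude away from the plateau — near-plateau points
destabilize the log regression); a small set of fallback starts guards
against a poor initial `k`, and the lowest-deviance converged fit is kept.
Constant or non-identifiable traces are flagged, never silently returned.
The H4-tail dependence is the fold ratio of k_obs on wild-type versus
tail-less H4 chromatin with propagated uncertainty; a non-saturated
denominator marks the fold an upper limit (`"<x-fold"`), following the
convention used for the published interface mutants. Replicate summaries
follow the source convention: s.d. for n ≥ 3, min/max for n = 2.

## Synthetic data: what it emulates and what it does not

The generators are seeded and emit their planted truth, so every
downstream stage can be scored exactly.

* `simulate_xl_ms()` plants crosslinked species with Gaussian ppm-scale
  mass error (default σ = 3 ppm, comfortably inside the 10 ppm window),
  20-fold +UV enrichment (matching the order of enrichment seen in
  extracted-ion-chromatogram quantifications), b/y ladders of stated
  completeness (default 80%) and log-normal intensities, plus Poisson
  decoy features/noise peaks. It does **not** emulate chromatographic
  profiles, deisotoping errors, co-eluting interference or raw instrument
  files — so passing tests demonstrate correctness of the search logic at
  stated error statistics, not robustness to upstream signal processing.
* `simulate_ensemble()` builds a three-helix Cα bundle (20 residues per
  helix, helices 6 Å from the bundle axis) threaded by an 8-residue
  peptide in a stated fraction of models and displaced ~60 Å in the rest,
  with 0.3 Å coordinate jitter. A generated toy receptor is used rather
  than any homology model because the latter depends on external template
  structures; the geometry gives a crisp planted pocket (13 residues at
  the 5 Å contact cutoff) while the large displacement makes restraint
  satisfaction unambiguous by construction. Real docked ensembles have
  correlated, much larger conformational variation; tests on this toy
  verify counting and filtering semantics, not docking realism.
* `simulate_kinetics()` produces exponential and linear traces with
  Gaussian noise; default problem sizes (40–60 points, 20-seed replicate
  studies) keep the full test suite under a minute while giving the fit
  recovery checks (median k error ≤ 5% at 5% noise) adequate power.

## Numerical choices and degenerate inputs

* Masses are double precision; candidate deduplication keys on sequences
  plus mass rounded to 12 significant digits.
* `match_ms1()` is exact (all-pairs within window), tested against a brute
  force oracle; windows are inclusive, so matching is symmetric and
  monotone in the window.
* Empty peptides, unknown residues and misplaced modifications are
  rejected with the offending position named. Bait peptides with zero or
  multiple photo-residues are excluded from candidate enumeration.
* A bound of 0 Å filters out every model; an empty restraint set retains
  all (vacuous satisfaction). Restraints referencing residues absent from
  the topology raise an error naming the restraint.
* Site-range strings accept the truncated shorthand used in print
  ("519-22" means 519–522).
* Tie-breaks: digest output is ordered by start then length; top-k contact
  residues by decreasing marginal with index order on ties.

## Known limitations

* The search assumes deisotoped, charge-resolved MS1 features (neutral
  mass or m/z + charge); no deconvolution is performed.
* One variable oxidation per peptide by default; heavier modification
  loads need explicit configuration.
* The tier rubric is a codification of a manual expert rating; its
  thresholds are defensible defaults, not a calibrated classifier.
* Contact surfaces treat models as an unweighted family, as the published
  analysis did; no pose energy or clustering weights are applied.
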