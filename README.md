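# xlmap

Mapping zero-length photo-crosslinks between proteins by mass spectrometry,
and turning them into structural and kinetic conclusions.

ISWI-family chromatin remodelers are inhibited by their own N-terminal
region (NTR) and activated by the histone H4 N-terminal tail. Where these
elements dock on the ATPase module can be mapped by photo-crosslinking:
a benzophenone — introduced genetically as *p*-benzoyl-phenylalanine
(Bpa, letter `B`) or chemically as a maleimidobenzophenone adduct on an
engineered cysteine (letter `X`) — inserts into a nearby C–H bond under
365 nm UV with **zero mass change**, so a crosslinked tryptic peptide pair
has neutral monoisotopic mass

    M(pair) = M(alpha) + M(beta)

exactly, which makes identification by accurate precursor mass (±10 ppm
MS1, ±15 ppm MS2) unusually clean. `xlmap` implements the full chain for
analysts working with such data:

* **Mass calculus** — modified/crosslinked peptide masses from elemental
  composition, ppm errors, m/z conversion, exact isotope patterns by
  convolution (`peptide()`, `crosslink_mass()`, `isotope_pattern()`).
* **Crosslink search** — tryptic digestion, candidate enumeration with
  variable Met oxidation, MS1/MS2 matching, b/y fragment assignment with
  the partner peptide as a rigid added mass, site localization with
  ambiguity intervals, UV-dependence quantification, and a deterministic
  high/medium/low reliability rubric (`search_crosslinks()`).
* **Restraint mapping** — crosslinks to 20 Å upper-bound Cα–Cα distance
  restraints (ambiguous ranges use any-of semantics, redundant linkages
  deduplicated), hard-filtering of docked model ensembles, and per-residue
  contact-probability surfaces written into PDB B-factors
  (`restraints_from_crosslinks()`, `filter_ensemble()`,
  `contact_surface()`).
* **Kinetics** — NADH-coupled ATPase turnover from linear absorbance
  windows, single-exponential remodeling rate constants k_obs
  (`y(t) = y∞ + (y0 − y∞)e^(−kt)`), H4-tail fold dependence with
  upper-limit flagging, saturation checks (`atpase_rate()`,
  `fit_single_exponential()`, `h4_dependence()`).
* **Simulators** — seeded generators for MS runs with planted crosslinks,
  docked ensembles with a planted binding pocket, and kinetic traces, each
  emitting its truth table (`simulate_xl_ms()`, `simulate_ensemble()`,
  `simulate_kinetics()`).

The package bundles machine-readable versions of the two reference
crosslink tables from the ISWI study it was designed around
(`reference_crosslinks("ntr")`, `reference_crosslinks("h4")`): sequences,
sites, observed masses and printed ppm errors.

## Worked example

Identify one published crosslink by mass: Bpa at ISWI position 483
(bait peptide `LDGQTPBEDRNR`, one missed cleavage) crosslinked to
`SPTKPK` (uncleaved K.P sites):

```r
library(xlmap)
xl <- crosslink_mass(peptide("LDGQTPBEDRNR"), peptide("SPTKPK"))
xl
#> <xl_species> LDGQTPBEDRNR -- SPTKPK  mass 2207.0971 Da
ppm_error(2207.0968, xl$mass)   # observed vs theoretical
#> -0.13
head(isotope_pattern(xl, 4))
#>       mass abundance
#> 1 2207.097 0.3072280
#> 2 2208.100 0.3598169
#> 3 2209.104 0.2291222
#> 4 2210.107 0.1038329
```

The theoretical pair mass lands 0.13 ppm from the observed 2207.0968 Da —
far inside the ±10 ppm search window — and, at 2.2 kDa, the second
isotopologue is already the base peak, as in the published isotopic
distributions. Reducing the five high-reliability H4-tail crosslinks to
distance restraints reproduces the published unique-linkage count:

```r
h4 <- reference_crosslinks("h4")
hi <- h4[h4$reliability == "high", ]
r  <- restraints_from_crosslinks(data.frame(
        alpha_chain = "H4",  alpha_site = hi$alpha_site,
        beta_chain  = "ISWI", beta_site  = hi$beta_site))
nrow(r)
#> [1] 3
```

## Analysis workflow

The `analysis/` scripts run the complete synthetic study end to end and
write tables under `results/`:

```sh
Rscript analysis/01_simulate.R            # inputs with planted truth
Rscript analysis/02_search_crosslinks.R   # reference mass audit + search
Rscript analysis/03_map_binding_pocket.R  # restraints -> filter -> surface
Rscript analysis/04_kinetics.R            # k_obs, H4 fold, ATPase rate
```

On the default seed the search recovers all planted crosslinks at 100%
recall, ensemble filtering retains exactly the pocket-placed models, the
contact surface recovers all 13 planted pocket residues, and the kinetic
fits return 16.7-fold H4-tail dependence (truth 16) and 2.500 s⁻¹ ATP
turnover (truth 2.5).

See `vignettes/crosslink-mapping.Rmd` for the model, parameter and design
discussion.

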