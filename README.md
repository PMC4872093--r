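# isprm

Target-recognition analysis for Type ISP restriction–modification
enzymes.

Type ISP enzymes are single-polypeptide restriction–modification systems
(nuclease + helicase-like ATPase + adenine-N6 methyltransferase + target
recognition domain) that methylate a specific adenine in their target
sequence and cleave unmodified DNA after ATP-driven translocation and
collision of two enzymes. Understanding how their MTase–TRD unit reads a
target such as `CTnGAyG` (LlaGI) versus `TnAGCC` (LlaBIII) — and how the
reading residues vary across the family — is the route to engineering
new sequence specificities. `isprm` is for structural bioinformaticians
and enzymologists working on that problem. It provides:

* **Structure I/O and the target frame** — PDB/mmCIF parsing into a flat
  atom table; the family's position convention (methylated T:A pair =
  +1, no position 0) anchored at an explicit residue
  (`load_structure()`, `assign_target_frame()`).
* **Contact mapping** — hydrogen-bond contacts between protein
  donors/acceptors and DNA within 3.5 Å, classified by side/main chain,
  base/sugar/phosphate moiety and major/minor groove; water bridges;
  intercalating planar side chains filling the flipped-base cavity
  (`detect_hbond_contacts()`, `detect_water_bridges()`,
  `detect_intercalation()`).
* **DNA deformation geometry** — windowed helical-axis fit, inter-arm
  bend angle, register-based major/minor groove widths, flipped-base
  detection (`duplex_geometry()` and friends).
* **Structure/sequence comparison** — Kabsch superposition,
  inter-domain rotation angles, global-alignment percent identity
  (`superpose()`, `interdomain_rotation()`, `pairwise_identity()`).
* **Alignment statistics** — Henikoff-weighted conservation with the
  flip-and-shift rescaling, mutual-information coupling with
  average-product correction (MI–APC), per-residue coupling strength,
  top-fraction selection, hypergeometric contact enrichment
  (`conservation_profile()`, `coupling_matrix()`, `top_fraction()`,
  `contact_enrichment()`).
* **Recognition code** — residue↔base-pair association tables across
  homologs scored by the purity product
  P(residue | pair) × P(pair | residue), and target prediction from
  anchor residues (`derive_code()`, `predict_target()`).
* **Translocation kinetics** — lag-phase triplex-displacement fits
  Y(t) = m·t for t < T_app, A(1 − e^(−k(t−T_app))) + C1 for t ≥ T_app
  with C1 = m·T_app, and the stepping rate k_step from the slope of
  T_app versus distance (`fit_trace()`, `fit_rate()`).
* **Synthetic generators with planted ground truth** for every stage
  (`make_duplex()`, `plant_contacts()`, `simulate_msa()`,
  `simulate_traces()`), plus a config-driven pipeline
  (`run_full_report()`).

## Worked example

```r
library(isprm)

# a synthetic complex: 24-bp duplex carrying the CTnGAyG-class target,
# with two pseudo side chains planted at 3.40 and 3.60 Å from base atoms
d  <- make_duplex(duplex_spec(paste0("ACGTACGT", "CTAGATG", "ACGTACGTA"),
                              plus_one = 10))
pc <- plant_contacts(d, data.frame(
  resname = c("LYS", "ASN"), resno = c(1131, 1228), atom = c("NZ", "ND2"),
  position = c(-2, 4), strand = c("bottom", "top"),
  base_atom = c("N7", "N7"), distance = c(3.40, 3.60)))
detect_hbond_contacts(pc$model, pc$frame)[,
  c("resno", "atom", "position", "moiety", "groove", "distance_A")]
#>   resno atom position moiety groove distance_A
#> 1  1131   NZ       -2   base  major        3.4
```

Only the 3.40 Å plant is reported: the 3.60 Å one sits beyond the 3.5 Å
hydrogen-bond cutoff, and the record classifies the contact as a
base-specific, major-groove interaction (lysine NZ donating to a purine
N7).

```r
# a 34° kink planted at the centre of a duplex is read back exactly
dk  <- make_duplex(duplex_spec(paste(rep("ACGT", 6), collapse = ""),
                               kink = list(step = 12, angle = 34)))
pos <- sort(unique(dk$frame$position))
bend_angle(dk$model, dk$frame, range(pos[1:8]), range(pos[17:24]))
#> [1] 34

# stepping-rate recovery: simulate lag-phase traces at 5 probe distances
# (true rate 226 bp/s, 2% noise), fit each trace, regress lag on distance
spec <- trace_spec(distances = seq(500, 3000, length.out = 5),
                   k_true = 226, C2 = 5, noise_sd = 0.02, seed = 1)
rec <- rate_recovery_experiment(spec, replicates = 10)
round(c(mean = rec$mean, sd = rec$sd), 2)
#>   mean     sd
#> 225.84   1.02
```

The recovered mean of 225.84 bp/s sits on the 226 bp/s ground truth —
the per-trace lag fit and the lag-versus-distance regression are
essentially unbiased at 2% signal noise.

## Documentation

The methods vignette
(`vignettes/target-recognition-methods.Rmd`) describes the models,
conventions, parameter choices and limitations in detail: the target
frame and partner assignment, the distance-only hydrogen-bond
criterion, the groove-width register convention, the MI–APC coupling
stand-in and its scope, the recognition-code statistic, the kinetic
model, and exactly what the synthetic generators do and do not emulate.
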