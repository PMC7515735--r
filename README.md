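# triplexkit

Modelling and stability metrics for GAA/TTC triple helices and
collapsed R-loops.

Expanded GAA/TTC trinucleotide repeats (the Friedreich's ataxia locus)
form non-canonical DNA structures: triple helices, in which a third
GAA or TTC strand binds the major groove of the GAA:TTC duplex through
Hoogsteen-type (H) or reverse-Hoogsteen-type (RH) hydrogen bonds, and
R-loops, whose RNA:DNA hybrid duplex can capture the displaced DNA
strand as a hybrid DNA·RNA:DNA triplex ("collapsed R-loop"). The same
two repeat sequences admit many non-equivalent topologies — 16 pure-DNA
conformations and 3 hybrid ones — and judging which of them hold
together requires metrics tailored to the third strand.

`triplexkit` is an R package for structural bioinformaticians working
on these systems. It provides:

* **Taxonomy** — enumeration of all 16 + 3 topologies in the label
  grammar `[p|ap][R|Y][(+)]?[-S]?[(a)|(s)]` (orientation, strand
  class, adenine protonation, register shift, glycosidic state), their
  per-plane triplet step types, and the two symmetry maps
  (*conformational* and *directional* counterparts) that organize
  them.
* **Builder** — idealized atomic models of any topology and of ideal
  A/B-form duplexes (DNA, RNA or hybrid), with third strands posed
  from idealized H/RH triad templates.
* **Stability metrics** — the effective hydrogen-bond number

  $$H^{\mathrm{eff}} = \sum_i H^{\mathrm{eff}}_i,$$

  counting only bonds between the third-strand base of plane *i* and
  duplex bases of the *same* plane (3.5 Å / 140° detection cutoffs),
  and the effective stacking area

  $$A^{\mathrm{eff}}_i = A^0_i(\cos\alpha_i - \sin\alpha_i), \qquad
    S^{\mathrm{eff}} = \sum_i \sqrt{A^{\mathrm{eff}}_i A^{\mathrm{eff}}_{i+1}},$$

  with $A^0$ = 4.95 Å² (T/C) or 8.29 Å² (A/G), $\alpha_i$ the
  third-strand base tilt against the Watson–Crick plane,
  $A^{\mathrm{eff}}_i$ forced to zero for $\alpha_i > 45°$ or
  $H^{\mathrm{eff}}_i = 0$ — so a perfectly stacked but detached
  strand scores zero.
* **Helical analysis** — base-pair step parameters, the Zp phosphate
  parameter, slide/Zp A–B classification, superposition RMSD,
  base-step overlap areas and triplex groove widths.
* **Pipeline** — per-frame metrics over multi-model PDB trajectories,
  2-D (H, S) stability histograms and a reproducible
  stable/marginal/unstable call.
* **Synthetic generator** — labelled trajectories (stable, detaching,
  base-flipping, stacked-but-detached) so the whole pipeline is
  testable without molecular dynamics.

## Worked example

```r
library(triplexkit)

spec <- parse_label("pY(a)")      # parallel TTC+ third strand, anti
tri  <- build_triplex(spec)       # idealized starting model
tri
#> <triplex_model> 3 strand(s), 27 residues, 402 atoms  [pY(a)]
#>   A: purine     DNA  n=9
#>   B: pyrimidine DNA  n=9
#>   C: third      DNA  n=9

effective_hbonds(tri)$total       # 2 template bonds on each of 9 planes
#> [1] 18
round(stacking_metrics(tri)$s_eff, 2)
#> [1] 39.6

# a synthetic run in which the third strand progressively detaches
traj <- generate_trajectory(spec,
          scenario_config("detaching", n_frames = 100, seed = 7))
met  <- analyze_trajectory(traj)
met
#> <frame_metrics> 100 frames [pY(a)]  H_eff: 1.6 +/- 3.9  S_eff: 2.5 +/- 8.6
stability_call(met)[c("call", "score")]
#> $call
#> [1] "unstable"
#> $score
#> [1] 0.06

# ideal A-form duplex classifies as A by slide/Zp
classify_form(build_duplex(strrep("GAA", 3), form = "A"))$aggregate
#> [1] "A"
```

The 18 hydrogen bonds are the two Hoogsteen-type bonds per triplet
plane of pY(a); 39.6 Å² is the coplanar stacking bound for its base
composition, which the idealized build attains. In the detaching run
only the first few frames keep the strand bonded, so the quadrant
score (fraction of frames with both metrics above half their
theoretical maxima) is 0.06 and the call is unstable.

Models and trajectories read and write multi-model PDB
(`read_triplex_pdb()` / `write_triplex_pdb()`; chains A/B/C = duplex
purine / duplex pyrimidine / third strand).

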