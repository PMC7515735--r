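---
title: "Modelling GAA/TTC triple helices and scoring third-strand stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling GAA/TTC triple helices and scoring third-strand stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triplexkit)
```

## The problem

Expanded GAA/TTC trinucleotide repeats in the first intron of the
frataxin gene adopt non-canonical structures — triple helices (H-DNA)
and R-loops — that interfere with transcription and underlie
Friedreich's ataxia. A triplex is a Watson–Crick duplex plus a third
strand bound in its major groove through Hoogsteen-type (H) or
reverse-Hoogsteen-type (RH) hydrogen bonds. Because the GAA strand is
all-purine and TTC all-pyrimidine, many distinct triplex topologies can
be assembled from the same two sequences, and an R-loop's RNA:DNA
hybrid duplex can additionally capture the displaced DNA strand as a
hybrid triplex (a "collapsed R-loop").

`triplexkit` does three things:

1. **enumerates** every non-equivalent topology (16 pure-DNA, 3 hybrid)
   with a compact label grammar and the symmetry relations between
   them;
2. **builds** idealized atomic starting models of any of them (and of
   ideal A/B-form duplexes);
3. **scores** conformations and multi-model trajectories with
   stability metrics designed specifically for the third strand, plus
   the standard helical-parameter analysis used to place hybrid
   duplexes on the A–B spectrum.

## The taxonomy

Eight base schemes exist: a pyrimidine (TTC) third strand parallel or
antiparallel to the duplex purine strand (`pY`, `apY`, cytosines always
N3-protonated — without protonation no stable bond to guanine can
form), and a purine (GAA) third strand parallel or antiparallel,
unshifted or shifted by one nucleotide, optionally with an
N1-protonated adenine meeting each G:C pair (`pR`, `apR`, `pR-S`,
`apR-S`, `pR(+)-S`, `apR(+)`). Each scheme is built with the
third-strand bases all-*anti* or all-*syn*, giving 16 conformations;
the label grammar is `[p|ap][R|Y][(+)]?[-S]?[(a)|(s)]`.

```{r}
specs_table(enumerate_dna_triplexes())[, 1:6]
```

Two symmetry maps organize the set. *Conformational* counterparts
reverse the third-strand direction **and** flip its glycosidic angles:
they present identical triplet steps with identical bond patterns
(pY(a) ↔ apY(s)). *Directional* counterparts reverse the direction
only: every H-type plane becomes RH-type (pY(a) ↔ apY(a)). For purine
third strands both maps also toggle the one-nucleotide register shift
(pR ↔ apR-S), which is what keeps the triplet steps aligned; the
published triplet summary table encodes exactly these pairings. Both
maps are involutions, verified exhaustively in the test suite.

Register conventions worth spelling out:

* A pyrimidine strand is a TTC repeat, but the repeat phase that places
  every (protonated) cytosine on a duplex guanine depends on the
  orientation: the parallel strand reads CTT-CTT-CTT 5'→3', the
  antiparallel one TTC-TTC-TTC (which reads CTT against the purine
  strand after reversal). Both phases are the same repeat; the choice
  makes all nine planes bond.
* A shifted purine register (`-S`) leaves one overhanging third-strand
  residue and one bare duplex plane; the overhang is built by
  continuing the helix one virtual plane beyond the duplex end.

The hybrid set is fixed by two constraints — the third strand bonds to
the purine strand of the hybrid duplex, and the two DNA strands of an
R-loop remain antiparallel — which leaves d(TTC⁺)·d(GAA):r(UUC) (apY),
d(GAA)·r(GAA):d(TTC) (pR) and d(GA⁺A)·r(GAA):d(TTC) (pR(+)-S), each
started from both B-like and A-like conformations (six build
requests).

## Building starting models

**Duplexes.** Bases are placed from standard-reference-frame
coordinates under fiber helical symmetry. The B form uses 36.0°
twist and 3.38 Å rise with no displacement or inclination; the A form
uses 32.7° twist, 2.81 Å rise, −4.4 Å x-displacement and +19°
inclination (classic fiber values; the sources describe starts only as
"ideal"/"standard", for which fiber geometry is the conventional
referent). The backbone is a reduced sugar–phosphate trace — P, C1',
O4', C2', and O2' on RNA — on which every implemented metric is well
defined; full fiber backbones are not reconstructible from the
information the package encodes and are not needed by any analysis
here. The phosphate position in the base-pair frame is a per-form
constant derived once by solving three fiber constraints (phosphate
radius, successive intra-strand P–P distance, canonical Zp: 8.91 Å /
6.7 Å / 0.1 Å for B, 9.4 Å / 5.9 Å / 2.2 Å for A) against the
package's own analysis code; the frozen values reproduce those targets
to within ~0.2 Å.

**Third strands.** Each third-strand base is posed on its triplet
plane from an idealized triad template: the initial H/RH donor–acceptor
pairs of its step type (shipped as an editable JSON registry under
`extdata`). Placement is an in-plane rigid fit refined in two stages:
first against ideal bond lengths with lone-pair/linearity regularizers
and a steric floor, then a *robustness polish* that maximizes the worst
detection margin across the template bonds, scoring bond length and
donor–H–acceptor angle in comparable noise units (thermal jitter of
0.1 Å per atom perturbs a bond length by ≈0.14 Å and an angle by
≈7.5°). Built bonds therefore sit near 3.0 Å and ≥165°, several noise
standard deviations inside the 3.5 Å / 140° detection cutoffs on every
bond rather than perfecting a subset. *Syn* states rotate the sugar
trace 180° about the glycosidic bond (equivalently, the base flips by
180° in χ); protonation adds the H3/H1 proton at cytosine N3 /
adenine N1. A clearance pass lets each sugar rotate a few degrees
within its χ well and relaxes phosphates locally so the reduced trace
respects a 2.0 Å heavy-atom floor; `count_clashes()` reports any
violations and the builder warns.

Two honest geometric limitations:

* the **RH-class A·A triad** (third-strand adenine flipped) cannot put
  both mutual N6–H···N7 bonds at 2.9 Å without atom overlap (an
  exhaustive in-plane scan bottoms out at 0.68 Å non-bonded
  separation); the builder keeps the two-bond template in least
  squares — one bond ≈2.9 Å, one ≈3.9 Å — and `idealize_hbonds()`
  reports the long bond as unsatisfied. The corresponding registers
  are also the ones whose simulations are reported least stable;
* **A-form triplex starts** keep a handful of backbone contacts just
  under the 2.0 Å floor (the rigid reduced sugar cannot thread a
  2.81 Å rise cleanly); the builder warns and no metric is affected.
  Ideal-A triplex starts are strained in full-atom work too.

`idealize_hbonds()` is a deterministic geometric refinement — iterative
rigid-residue translations down the gradient of squared template-bond
violations — standing in for restrained equilibration: only the
geometric intent (template bonds formed where sterically possible)
matters downstream.

## The stability metrics

Simply counting hydrogen bonds misleads: bonds linking bases on
*different* planes do not stabilize a triplex, and a perfectly stacked
but detached strand would score well on overlap area. The two metrics
are built to resist both failure modes.

**Effective hydrogen-bond number.** Bonds are detected with a 3.5 Å
heavy-atom donor–acceptor cutoff and a 140° donor–H–acceptor cutoff.
$H^{\mathrm{eff}}_i$ counts only bonds between the third-strand base of
plane $i$ and the duplex bases of the *same* plane;
$H^{\mathrm{eff}} = \sum_i H^{\mathrm{eff}}_i$. Bifurcated bonds count
as distinct donor–acceptor pairs; two hydrogens of one amino donor do
not double-count a pair.

**Effective stacking area.** With $\alpha_i$ the angle between the
third-strand base normal and the pooled Watson–Crick pair normal of
plane $i$ (unsigned, folded to [0°, 90°] — the cutoff below makes an
unsigned convention the only coherent one):

$$A^{\mathrm{eff}}_i = A^0_i(\cos\alpha_i - \sin\alpha_i),$$

with $A^0_i$ = 4.95 Å² for T/C (and U) and 8.29 Å² for A/G (G takes
the purine value). The cosine projects the ring onto the pair plane
(parallel stacking); the sine penalizes T-shaped stacking. Two forcing
rules apply: $A^{\mathrm{eff}}_i = 0$ for $\alpha_i > 45°$ (the formula
itself crosses zero exactly at 45°, so the metric is continuous), and
$A^{\mathrm{eff}}_i = 0$ whenever $H^{\mathrm{eff}}_i = 0$ — the
coupling that forces the stacked-but-detached pathology to zero. Steps
combine as a geometric mean,
$S^{\mathrm{eff}}_i = \sqrt{A^{\mathrm{eff}}_i A^{\mathrm{eff}}_{i+1}}$,
and $S^{\mathrm{eff}} = \sum_i S^{\mathrm{eff}}_i$, so a single broken
plane interrupts both adjacent steps. The coplanar fully-bonded bound
$\sum_i \sqrt{A^0_i A^0_{i+1}}$ and the template bond count serve as
per-topology maxima for normalized scores.

```{r}
m <- build_triplex(parse_label("pY(a)"))
c(H_eff = effective_hbonds(m)$total,
  S_eff = round(stacking_metrics(m)$s_eff, 2))
```

**Pattern classification.** Per-plane bond sets are matched against the
initial H/RH template and a registry of named variants (bifurcated
guanine bonds, the duplex-crossing adenine pattern, and so on);
anything else is reported verbatim as a novel pattern, and
`pattern_timeline()` aggregates occupancies along a trajectory.

## Helical parameters and A/B classification

Base frames are fitted by superposing standard ring coordinates on the
observed rings; strand-II frames are flipped about x; pair frames are
geodesic means; steps use the symmetric mid-frame decomposition
(twist/roll/tilt/shift/slide/rise plus screw-axis helical twist, rise
and inclination). Zp is the mean z-coordinate of the two step
phosphates in the mid-frame, with the strand-II phosphate expressed in
the dyad-flipped frame as for every strand-symmetric step parameter (in
an ideal fiber the naive average is identically zero by dyad symmetry).
Classification uses the two discriminating parameters: A-form if
slide < −0.8 Å and Zp > 1.5 Å, B-form if slide > −0.8 Å and
Zp < 0.5 Å, otherwise intermediate. Overlap areas clip convex base-pair
outlines projected on the mid-step plane (validated against a
Monte-Carlo sampling oracle); groove widths are minimal inter-strand
P–P distances minus the conventional 5.8 Å phosphate correction. On
built starting models the parallel-strand ordering (third↔GAA groove
narrowest) reproduces; antiparallel groove ordinals describe
equilibrated backbones and are outside what the schematic trace
reproduces.

```{r}
colMeans(step_parameters(build_duplex(strrep("GAA", 3), form = "A")))[
  c("twist", "rise", "slide", "Zp")]
```

## Trajectories, histograms, stability calls

`analyze_trajectory()` evaluates the per-plane metrics frame by frame
(a precomputed candidate-pair table makes this fast); `histogram2d()`
bins $(H^{\mathrm{eff}}, S^{\mathrm{eff}})$ with left-closed integer /
1 Å² bins; `stability_call()` reports the fraction of frames in the
upper-right quadrant — $H^{\mathrm{eff}} \ge h^* H_{max}$ and
$S^{\mathrm{eff}} \ge s^* S_{max}$ with $h^* = s^* = 0.5$ — and calls
stable at score ≥ 0.8, unstable below 0.2, marginal between. The
thresholds are normalized per topology because base composition changes
both maxima. Published stability judgements of this kind are made
visually from the histograms; these numeric cut points are an explicit,
reproducible proxy and are exposed as arguments.

## The synthetic generator

`generate_trajectory()` produces labelled test beds for the whole
pipeline: frame 1 is the idealized build, later frames add independent
per-atom Gaussian jitter (default σ = 0.1 Å, a typical heavy-atom
thermal amplitude at the frame spacing of interest) plus a scenario
transform:

* **stable** — jitter only;
* **detaching** — rigid third-strand displacement along the groove-exit
  vector (duplex axis → third-strand centroid, ⊥ axis) at 0.15 Å/frame,
  so a 100-frame run loses its bonds within the first few frames and is
  cleanly separated from the stable case;
* **flipping** — scheduled 90° base flips about the glycosidic bond
  (default: planes 3–7 from frame 11 — a majority of planes, a
  ground-truth unstable case);
* **stacked_detached** — a rigid translation along the helix axis
  clearing the whole duplex (a sideways rigid move cannot clear a
  strand that wraps around the helix), preserving internal stacking
  exactly while zeroing every in-plane bond.

Ground-truth labels (attached/flipped per plane per frame) are
evaluated on the noise-free transformed geometry. Everything is
reproducible from the seed.

What the generator does *not* emulate: real dynamics (no velocity
correlation, no solvent, no temperature dependence, no gradual
hydrogen-bond isomerization). Passing the label-recovery suite
therefore shows that the metrics separate the four geometric failure
modes they were designed for — not that they rank the stability of real
trajectories, which requires real sampling.

## Problem sizes and numerical choices

The test and acceptance workloads use three repeats (nine nucleotides
per strand, the construction size of the source models), 100-frame
trajectories and five seeds per scenario — comfortably informative for
metrics that are frame-wise deterministic. Tolerances: plane fits and
frame fits are exact least squares; the triad optimizer is multi-start
Nelder–Mead (deterministic); detection cutoffs are the fixed 3.5 Å /
140°; degenerate inputs (fewer than two planes, missing phosphates,
residues without ring atoms) degrade to warnings with the affected
plane excluded. Terminal planes can be excluded from aggregate metrics
(`exclude_terminal`), mirroring end-restraint conventions; the default
keeps all planes.
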