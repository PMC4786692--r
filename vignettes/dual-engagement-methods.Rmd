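---
title: "Geometry, stoichiometry and binding models for dual-domain-antibody engagement"
author: "dualreach"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry, stoichiometry and binding models for dual-domain-antibody engagement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualreach)
```

## The scientific question

A dual-domain antibody (dual dAb) is an Fc homodimer carrying two distinct
single-domain antibodies per monomer: a VH domain fused through a peptide
linker at each Fc N-terminus and a Vκ domain at each Fc C-terminus. Both
domains bind the same antigen, a two-fold symmetric homodimer (VEGF-A) that
presents two equivalent epitopes. Such a molecule has four binding sites and
the antigen has two, so many complex topologies are conceivable. The question
this package addresses quantitatively is: *which topologies can the molecule
actually adopt, and what complexes should therefore appear in solution?*

The evidence comes from three orthogonal desk-scale analyses, each a module
here:

1. **Structure geometry** (`read_structure`, `superpose_on_antigen`,
   `terminal_distances`): two independently solved antigen/domain co-crystal
   structures are placed in one frame by least-squares superposition on the
   shared antigen, and the separations between the domain termini that
   connect to the Fc linkers are measured. Three distances matter: between
   the two VH C-termini (both "top" attachment points), between the two Vκ
   N-termini ("bottom"), and the cross distance from a VH C-terminus to the
   Vκ N-terminus at the opposite epitope.
2. **Linker reach** (`coengagement_feasibility`,
   `classify_engagement_mode`): whether the peptide linkers can bridge each
   separation decides between an *end-on* mode (one antigen clamped by the
   two like domains at one end of the molecule) and a *side-on* mode (each
   half of the molecule clamps its own antigen laterally with one VH and
   one Vκ), the latter allowing one molecule to trap two antigen dimers.
3. **Solution stoichiometry** (`enumerate_species`, `match_species`,
   `mass_profile`): the species that the feasible topologies predict are
   compared with absolute molar masses measured by SEC-MALLS, inverted from
   multi-detector traces via the zero-angle Debye-Zimm relation.

Supporting binding models (`fit_one_to_one`, `fourpl_fit`,
`equilibrium_competition`, `capacity_curve`) cover the kinetic and
competition measurements that accompany such a characterization.

## Geometry

`kabsch_superpose` implements the closed-form least-squares rigid
superposition: the SVD of the cross-covariance of the centered point sets,
with the determinant correction that excludes improper rotations. Antigen
chains are matched C-alpha by C-alpha on identical residue numbers — the
deposited antigen chains of such structure pairs share numbering, so no
sequence alignment is attempted. An antigen RMSD above a configurable sanity
cap (default 5 Å) flags the superposition rather than failing it: a
distorted antigen is a data problem the user should see, not a crash.

"Terminus" always means the first or last *resolved* residue with a
C-alpha. Crystal structures routinely lack density for flexible termini, so
this is the only definition measurable from deposited coordinates; a
terminal residue lacking a C-alpha falls back to the nearest resolved
residue that has one. Distances measured this way are therefore lower-bound
anchors for the linker analysis, an assumption the reach thresholds absorb.

For multi-model files only the first model is used, and only altloc `A` (or
blank), so geometry is deterministic. Waters are excluded; resolved tag
residues are kept.

`solvent_content` is the standard Matthews calculation: cell volume by the
general triclinic formula, Matthews volume $V_M = V_{cell}/(Z M)$, solvent
fraction $1 - 1.23/V_M$ with the conventional protein packing constant
1.23 Å³/Da. It serves as a sanity check that a proposed asymmetric-unit
composition is consistent with the crystal cell.

## Linker reach and engagement mode

The reach model is deliberately coarse, because it only needs to separate
"easily spanned" from "requires near-full extension". A linker of $n$
residues contributes at most its contour length $n \times 3.5$ Å (an
extended peptide spans 3.4–3.8 Å per residue; 3.5 is the package default and
both numbers are arguments). A pair of linkers plus the separation of their
anchor points on the scaffold gives the available span; the verdict is
graded by the *extension fraction* (required/available):

* ≤ 0.75 — `feasible`: comfortably reachable by a flexible linker;
* ≤ 0.95 — `marginal`: only an extremely extended, entropically
  improbable conformation would reach;
* above — `infeasible`.

The thresholds are package choices (the underlying observation is stated as
a conclusion, not a cutoff) and are exposed as arguments. The default
architecture uses 15-residue linkers: the real molecule's linker sequences
are not public, so these defaults are explicit, stated parameters rather
than measurements. The anchor allowances differ by pair: the two Fc
N-termini sit together at the hinge (0 Å), while the Fc C-termini
contribute a small allowance (10 Å default).

With the default parameterization and the measured 81/70/77 Å distances:
the VH–VH top clamp needs 77% extension (marginal — effectively ruled
out), while the Vκ–Vκ bottom clamp (61%) and the cross VH–Vκ pair (67%) are
comfortable. The headline classification is *end-on* only if both
like-domain clamps are feasible, *side-on* if the cross pair is feasible
while VH–VH is not. That is the package's formalization of the argument
that the side-on mode, in which each molecule traps two antigen dimers, is
the likely engagement.

```{r}
classify_engagement_mode(list(d_vh_vh = 81, d_vk_vk = 70, d_cross = 77),
                         dual_dab_architecture())
```

## Species enumeration

`enumerate_species` generates every connected complex of up to
`max_binders` molecules and `max_antigens` antigen units in which each
binding site and each epitope carries at most one bond, subject to
`feasibility_rules` distilled from the reach analysis:

* `clamp_pairs` — which site-type pairs of one molecule may occupy both
  epitopes of the same antigen (dual dAb default: VH+Vκ and Vκ+Vκ; VH+VH
  forbidden);
* `intermolecular` — whether two molecules may share one antigen unit
  (off by default for the dual dAb: the ~370 kDa twinned species such
  sharing predicts is not observed);
* `require_clamp` — whether engagement is avid, i.e. every bound antigen
  is clamped at both epitopes (on for the dual dAb, off for a
  conventional IgG, whose single-epitope attachments are what lets
  chains and rings grow).

Duplicates are removed by canonical labelling over the full symmetry group:
permutations of binder molecules, of antigen units, and of the equivalent
scaffold copies within each molecule. Epitope labels are not part of a
species' identity (the two epitopes of a homodimer are equivalent), but
*which scaffold copy* a bond uses is: a complex clamped by the VH and Vκ of
the same monomer is a different topology from one clamped across monomers,
and the catalog keeps both. Site types must be unique within a scaffold
copy for this quotient to be exact. A configurable exploration cap turns
runaway enumerations into an explicit overflow error.

Under dual-dAb rules the closed species are exactly the 1:1 and 1:2
complexes — the molecule saturates at two antigen dimers — whereas IgG
rules produce the open-ended n:n ring/chain series (2:2, 3:3, ...), the
qualitative difference between the two SEC-MALLS profiles.

`species_mass` is the plain arithmetic sum of component masses (109 kDa
binder, 48 kDa antigen dimer by default), and `match_species` ranks
catalog compositions against an observed mass or mass interval within a
relative tolerance of 15%, the conventional accuracy band for SEC-MALLS
conjugate masses.

## SEC-MALLS forward model and inversion

The forward model (`simulate_chromatogram`) is the ideal dilute-limit
behaviour of the three detectors for Gaussian elution bands: refractive
index $ri = c \cdot dn/dc$, UV absorbance $uv = 1000\,c\,\varepsilon$, and
excess Rayleigh ratio $R_\theta = K^* c M$ at zero scattering angle with
$K^* = 4\pi^2 n_0^2 (dn/dc)^2/(\lambda^4 N_A)$. The second virial term of
the Debye-Zimm expansion is dropped: the analysis reports masses, not
virial coefficients, and at typical injection concentrations the correction
is far below the 10–15% matching band. The default $dn/dc$ of 0.185 mL/g is
the protein convention.

Inversion (`mass_profile`) recovers $c(t) = ri(t)/(dn/dc)$ and
$M(t) = R_\theta(t)/(K^* c(t))$ wherever $c$ exceeds a floor (default 2% of
the maximum), masking the rest: below the floor the division is by detector
noise. Interdetector delays are estimated by cross-correlation against the
light-scattering trace and removed (`align_detectors`); a flat correlation
leaves the data untouched with a warning.

Per-peak masses (`peak_mass_table`) are amount-weighted means over the
peak, $\sum c M / \sum c$, which algebraically reduces to a ratio of summed
detector signals — noise averages out across the band instead of being
amplified pointwise. Peaks are detected on the concentration trace (the
concentration proxy), not the mass-weighted scattering trace. On noiseless
synthetic data the forward/inverse pair is exact to numerical precision;
with noise at a signal-to-noise ratio of 50 the peak mass stays within 3%
across seeded replicates — the package's own test conditions.

The mixing-series generator assigns injected material to species by
simplified occupancy rules per scenario (dual dAb: closed 1:1/1:2 only;
IgG: a fixed-weight ladder of n:n networks; trap: strict 1:1) and a
log-linear retention model. These are *assignment* rules, not
self-assembly physics: the package's claims are about the detection,
inversion and matching logic, and passing tests do not validate any
polymerization kinetics. Real chromatograms additionally show band
broadening, column interactions and baseline drift that the generator does
not emulate.

## Binding models

`kd_from_rates` is the Langmuir identity $K_D = k_d/k_a$, reported in pM to
3 significant figures as kinetics tables print it.

`simulate_sensorgram`/`fit_one_to_one` implement the 1:1 model: association
$R(t) = R_{max}\frac{C}{C+K_D}(1-e^{-(k_a C + k_d)t})$ and exponential
dissociation from the association endpoint. The fit is global across the
concentration series — one $(k_a, k_d, R_{max})$ triple for all curves — by
Levenberg-Marquardt on log10 parameters with a small multi-start grid, for
reproducibility of convergence. Mass-transport and bivalent-analyte
effects are ignored, matching how such data are routinely evaluated; a
`drop_top` flag reproduces the common practice of discarding the highest
concentration when it misbehaves. Under-determined designs (fewer than
three concentrations, or one saturating curve) warn of ill-conditioning
rather than failing.

`fourpl_fit` is the four-parameter logistic ("sigmoidal dose response,
variable slope"); decreasing curves are fitted with a negative slope and
flagged inverted, the inflection dose then being an IC50.

`equilibrium_competition` solves, per inhibitor concentration, the
free-antigen conservation equation for a pool of independent, equivalent
inhibitor sites against a non-depleting receptor probe, by bisection to
near machine precision; the IC50 is extracted from the resulting inhibition
curve with the 4PL. The per-site affinity and the per-molecule capacity
(`dimers_trapped`) are deliberately separate parameters so avidity and
stoichiometry can be varied independently. The package does not attempt to
reproduce absolute assay IC50s — they depend on assay constants the model
does not know — but in the tight-binding (stoichiometric) regime it
verifies the capacity prediction: a molecule trapping two antigen dimers
needs half the molar concentration of a one-dimer trap, the IC50 ratio
approaching 2. Mass-to-molar conversions always require an explicit molar
mass (`ngml_to_molar`): a "ng/mL" figure is meaningless without one.

## Synthetic fixtures and what tests do (and do not) show

`make_toy_complex` builds idealized poly-alanine C-alpha structures: a
two-fold symmetric antigen homodimer with binder domains whose termini are
*constructed* at the configured separations (defaults 81/70/77 Å, the
measured layout). The construction places termini on a C2 axis and solves
for the out-of-plane lift that realizes the cross distance; geometrically
impossible combinations raise an error. All generators are pure functions
of their configuration and seed — equal seeds give bit-identical files —
and each writes a ground-truth manifest so recovery tests never read truth
from the simulated signal path.

Because the toy structures are exact by construction, geometry tests
validate the measurement pipeline, not the published coordinates; running
the same pipeline on the deposited structures requires downloading them,
which the package supports (`read_structure` on any PDB/mmCIF file) but
does not do on its own.

## Numerical choices and problem sizes

* Superposition: SVD with determinant correction; collinear inputs are
  rejected as ill-conditioned.
* Equilibrium solves: bisection with tolerance ~1e-14 relative; antigen is
  conserved to better than 1e-9 at every reported point.
* Optimizers: `minpack.lm` Levenberg-Marquardt, log-parameterized,
  multi-start; noiseless round trips recover parameters to ≤0.1%.
* Enumeration: exhaustive with canonical-label dedup; default tests run to
  limits (3,3), where the implementation is cross-checked against an
  independent brute-force/graph-isomorphism oracle.
* Simulation sizes in the tests: 901-point chromatograms, 100-replicate
  noise studies, 20-replicate fit studies, a 4-point KD grid from 1 pM to
  10 nM — sizes chosen so the full suite runs in a few minutes on one core.

## Known limitations

* The reach model treats linkers as straight segments with a contour-length
  budget; no conformational sampling, no excluded volume, no Fc geometry
  beyond the anchor allowances.
* Enumeration labels species by composition and connectivity only; it does
  not weight them thermodynamically or kinetically.
* The SEC-MALLS model omits band-broadening deconvolution, column
  calibration and form-factor (angular) analysis; it is a zero-angle
  treatment.
* The competition model assumes independent equivalent sites and a
  non-depleting receptor; cooperative or depleting regimes are out of
  scope.
* Linker lengths of the real molecule are placeholders; conclusions that
  depend on them (the marginal/feasible boundary) should be re-run with
  actual lengths when known.
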