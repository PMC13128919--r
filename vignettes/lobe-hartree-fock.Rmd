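---
title: "Screened lobe-function Hartree-Fock: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screened lobe-function Hartree-Fock: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`lobehf` implements restricted, closed-shell Hartree-Fock in a minimal
basis in which *every* basis function is a linear combination of s-type
Gaussian primitives. s shells are the standard minimal-basis
contractions. A p orbital is represented by six displaced s primitives:
three with coefficient $+A_a$ displaced by $+d_a$ along the orbital
axis and three mirrored with $-A_a$, with $d_a = k/\sqrt{\alpha_a}$.
The antisymmetric arrangement produces the nodal plane exactly; no
Cartesian prefactors and no angular-momentum recursions appear
anywhere. The payoff is uniformity: overlap, kinetic,
nuclear-attraction and electron-repulsion integrals each have one
closed form, and the two-electron kernel is

$$(g_a g_b|g_c g_d) \;=\; O_{ab}\, O_{cd}\, \sqrt{P}\,
  {}_1F_1\!\left(\tfrac12, \tfrac32, -P\, d_{ab,cd}^2\right),$$

with the pair factor $O_{ab} = \sqrt{2}\,\pi^{5/4} A_a A_b
(\alpha_a+\alpha_b)^{-3/2} e^{-\mu_{ab}|r_a - r_b|^2}$, the reduced
exponent $P = [(\alpha_a{+}\alpha_b)^{-1} +
(\alpha_c{+}\alpha_d)^{-1}]^{-1}$ and $d_{ab,cd}$ the distance between
the exponent-weighted composite centers. The $\sqrt{P}$ prefactor is
fixed by the exact s-Gaussian ERI; we verified it against an
independent quadrature built on the Gaussian integral transform of
$1/r_{12}$, which reduces the 6D integral to a 1D adaptive quadrature
with purely Gaussian inner integrals and no erf anywhere.
${}_1F_1(\tfrac12,\tfrac32,-x) =
\sqrt{\pi}\,\mathrm{erf}(\sqrt{x})/(2\sqrt{x})$ is evaluated through
the C library `erf` by default. The five-term rational erf
approximation with the $x \ge 4 \Rightarrow 1$ shortcut (tail error
$1-\mathrm{erf}(4) \approx 1.5\times10^{-8}$) is implemented and
contract-tested as `erf_approx()`; we keep machine-precision erf in
the engine because it costs the same on current hardware and preserves
$10^{-10}$-level agreement with conventional references on s-only
systems.

## Basis tabulations

Reference data ship as plain-text Gaussian-dialect tables. For H, He,
C, N and O the STO-3G exponents and contractions are the standard
published values. The STO-6G tables (and the third-row STO-3G entries
for S and P) are *generated* by the package's own overlap-maximizing
fits of Gaussian expansions to node-less Slater orbitals
(`fit_sto_expansion()`, `fit_sto_expansion_sp()`), scaled by per-shell
Slater exponents; the file headers say so explicitly. Two details
matter and are tested:

* the ns and np shells of a period share one exponent set (the
  published convention); the shared-exponent fitter reproduces the
  published universal STO-3G 2sp expansion to 5-6 decimals, which
  validates both the code and the fit criterion;
* in the shell-wise inner products the angular factor $r^l$ belongs to
  the integration weight $r^{2+2l}$, not to the radial profiles — with
  the profiles carrying it too, p fits silently minimize an
  $r^6$-weighted functional and come out far too diffuse.

## The p representation used for energies

Two constructions of the six-lobe set coexist:

* **Primitive splitting** (`split_p_shell()`, the default for
  three-primitive tabulations): each tabulated Cartesian primitive
  $x\,e^{-\alpha r^2}$ is split into a mirrored pair $\pm A\,
  e^{-\alpha|r \mp d\hat e|^2}$ with $d = k/\sqrt{\alpha}$ and $A$
  matching the pair to the primitive at leading order (the pair equals
  $2A e^{-\alpha d^2} e^{-\alpha r^2}\sinh(2\alpha d x)$, so the
  relative error is $O(k^2)$). With the default $k = 0.03$ the basis
  deviates from its conventional Cartesian counterpart by fractions of
  a milli-hartree — water agrees with a conventional reference to
  0.013 mHa in the total energy and 0.22 mHa RMSD in orbital energies,
  and single-carbon p ERIs agree to $\sim 10^{-4}$ — while the signed
  amplitudes stay $O(10)$, so no precision is lost to cancellation.
* **Grid fitting** (`fit_lobe_p_orbital()`): exponents and one shared
  $k$ optimized by Nelder-Mead against the STO-6G reference p on a
  $61^3$ cube of half-width $6/\sqrt{\min\alpha}$, coefficients solved
  linearly, contraction renormalized. Typical relative L2 error is
  1.2-1.5%. This is the construction used for the STO-6G family
  (keeping six primitives per p function) and the source of the cached
  parameter table. A free fit necessarily lands $\sim 1\%$ away from
  the *tabulated* three-Gaussian p (the fit metric differs from the
  tabulation's), which costs tens of mHa on p-rich molecules; that is
  why the splitting construction, which inherits the tabulated
  exponents and coefficients exactly, is the default energy
  representation. $k$ is bounded away from zero in the fit because the
  $k \to 0$ derivative limit fits equally well but needs divergent
  coefficients.

Fitted parameters are cached in a versioned table
(`inst/extdata/basis/lobes.dat`) keyed by element and shell; absent
entries are fitted on the fly.

## The relevance representation

Density-relevance screening needs $\int |\varphi_i \varphi_j|$, and
the signed lobe expansion cannot provide it (term-wise absolute values
do not reproduce the absolute orbital). Each lobe of the p function is
therefore represented by six all-positive, axially symmetric Gaussians
$A\,e^{-a_x (x-x_0)^2 - a_p(y^2+z^2)}$
(`fit_abs_lobe_representation()`); the mirrored lobe carries the
opposite sign and offset, and relevance integrals evaluate these
representations with general 3x3 quadratic forms, which keeps them
exactly rotation-covariant.

The fit objective is evaluated **entirely from closed-form inner
products** — the signed combination (lobe minus mirror) must reproduce
the p orbital, and the positive sum (lobe plus mirror) its absolute
value. We abandoned grid-sampled objectives after finding that they
admit spuriously sharp primitives hiding between grid points: a
solution scoring "3% L1" on its fitting grid had an analytic two-lobe
norm of 5.35 instead of 1, which would have silently disabled the
density screen. The fit is performed at a canonical exponent scale and
transformed back (the problem is exactly scale-covariant), so scaled
shells give identical-quality representations.

Measured quality: the achievable signed-reconstruction error of an
all-positive two-lobe split is floored by Gaussian leakage across the
nodal plane at about 6-7% L1/L2 (we scanned 4-8 primitives per lobe);
the self-relevance of a p function — the quantity the screen actually
thresholds — integrates to within ~2% of the exact $\int|\varphi|^2 =
1$. Tests assert these measured bounds. For screening decisions at
thresholds of $10^{-4}$ to $10^{-6}$ a few percent of shape error is
immaterial.

# Screening

Two tiers control the two-electron work:

* **Density cut-off** $\tau_\rho$ (default $10^{-4}$; $10^{-6}$ for
  spectra): a basis-function pair survives when its relevance
  $r(\rho_{ij})$ reaches the threshold. Self-pairs always survive.
* **Coulomb cut-off** $r_{cl}/r_{cu}$ (default 8/10 Å): interactions
  between density pairs are kept in full below $r_{cl}$, dropped above
  $r_{cu}$, and scaled by $f(x) = 1 + 2x^3 - 3x^2$ in between. Each
  density's position is the arithmetic mean of its two host atoms. The
  C1 switching keeps the truncated energy differentiable; for gradient
  work $r_{cu} \gtrsim 2.5\, r_{cl}$ keeps the switching-region force
  below the unswitched force (tested on a two-charge model).

A third, combined test ($r_i r_j / d \ge \tau_f$, with a 0.1 bohr
distance floor) is implemented but disabled by default: no standard
value for $\tau_f$ exists, and we will not silently drop integrals
based on an invented threshold.

The smoothing weight multiplies each integral once, wherever it enters
— Coulomb and exchange alike — which keeps the Fock matrix symmetric
and the energy well-defined. The same window switches the
nucleus-nucleus repulsion; electron-nucleus attraction is never
truncated.

Truncating the Coulomb interaction is a *model change*, not a small
perturbation, and on unfavourable systems it has real consequences: on
a fully extended vacuum polyglycine chain (a row of aligned amide
dipoles twice as long as the window) the 8/10 Å default drives the
self-consistent state into distorted, bistable polarization patterns.
Solvated or globular systems are far more forgiving. Quantities that
need accuracy — binding energies, reference comparisons — should use a
large or disabled window, which is also the recommendation we inherit
for force calculations.

# SCF

Core-Hamiltonian guess (a `read` guess is accepted for restarts);
canonical orthogonalization dropping overlap eigenvalues below
$10^{-7}$; convergence on the per-element density RMSD
$\sqrt{\sum \Delta P^2 / n_{bf}^2} < 10^{-6}$. The driver has two
stages: damped startup followed by Pulay (DIIS) extrapolation, and —
if DIIS fails to settle, which truncated-interaction Fock operators
are prone to on peptide fragments — an automatic restart with heavy
damping (0.7) and a virtual level shift, slow but reliably
contractive. A 0.3 Ha level shift also guards the accelerated stage
while the density is far from self-consistency and is released near
convergence. Restricted closed-shell only: odd electron counts are a
hard error, consistent with the capping rules always producing even
counts.

# Divide-and-conquer

Cores come from seeded k-means++/Lloyd clustering (heterogeneous
systems) or a half-open uniform grid anchored at the bounding-box
minimum (12.5 Å default edge; homogeneous solvated systems). Buffers
collect all atoms within 8-10 Å of a core. Bonds are detected at 1.3x
the summed covalent radii; cut double bonds (C-C < 1.40 Å, C-O < 1.28,
C-N < 1.32) pull both atoms in, iterated to fixpoint; cut single bonds
are terminated by a hydrogen at the standard X-H length (C-H 1.09,
N-H 1.01, O-H 0.96, S-H 1.34 Å) along the former bond. Clusters are
neutral; charged residues are an acknowledged approximation. Clusters
are solved strictly sequentially — fully independent, no inter-cluster
coupling or charge embedding — so peak memory is one cluster's.

Merging: an element whose two host atoms share a core comes verbatim
from that cluster (so a degenerate single-cluster partition reproduces
the full density matrix exactly — a regression test). An element
spanning two cores is interpolated: the segment between the atoms is
cut by the border (shared cell face for grid partitions; perpendicular
bisector plane of the centroids for k-means and non-adjacent cells),
the two sub-lengths are normalized to sum to one, and each cluster's
contribution is weighted by the *other* side's length. Without a
defined crossing the arithmetic mean is used. Split elements are
enumerated down to a relevance of $10^{-6}$; density-matrix elements
decay more slowly than overlaps, so the few gated-out far elements
(up to $\sim 10^{-2}$ in magnitude) contribute only through similarly
tiny integrals.

The total density $\rho(r) = \sum_{ab} r(a,b) P_{ab} \rho_{ab}(r)$
uses a 0/1 relevance indicator at the screening threshold. Grid
evaluations resolve valence structure at the default 1.5 bohr spacing;
the products of core 1s functions are orders of magnitude sharper than
any practical grid, so quantitative electron counts on grids are
checked against the analytic integral of the valence-only density.
System-wide molecular orbitals, HOMO/LUMO and band gaps are
deliberately out of scope under divide-and-conquer; per-cluster
orbital-energy lists are retained and never merged.

The fidelity benchmark compares per-atom energies between a full
calculation and a two-cluster divide-and-conquer run on capped
tetraglycine (124 basis functions — large enough that full HF is still
its own oracle). With the standard density screen and no Coulomb
window the agreement is Pearson > 0.9999 with 0.015% relative RMSD;
the comparison deliberately excludes the Coulomb window because, on
this artificial extended chain, truncation pathology (above) would
otherwise dominate what is meant to measure partitioning and capping
fidelity.

# Real-time TDHF

The converged density is excited by a length-gauge Gaussian pulse
(strength $10^{-5}$ a.u., $\sigma = 0.2$ a.u., start 2 a.u.) and
propagated 2000 steps of 0.25 a.u. (12.1 fs) with an enforced-unitary
exponential midpoint scheme: the Fock matrix at the half step comes
from one predictor-corrector cycle and is exponentiated exactly in the
orthonormal basis. Unitarity makes Tr(PS) conservation a structural
property, asserted to $10^{-6}$. The task list is frozen at $t = 0$.
One implementation subtlety deserves a warning to future maintainers:
the two-electron build must *not* symmetrize its output, because the
imaginary part of the Hermitian density is antisymmetric and its
exchange term legitimately antisymmetric — symmetrizing silently
removes the entire two-electron response (the H2 peak then appears
7 eV too high; with the correct build it matches an independent
linear-response RPA calculation to better than 0.001 eV).

The absorption intensity is $\omega\,\mathrm{Im}\,\alpha(\omega)$ with
$\alpha$ the damped ($\gamma = 0.01$ a.u.) Fourier transform of the
induced dipole divided by the analytic pulse transform; resolution is
$2\pi/(N\,\Delta t)$, no zero padding. Excitation energies are finally
*divided* by 1.335: the calibration maps systematically overestimated
TDHF energies onto experiment, and dividing the energy axis is the
reading consistent with that direction (multiplying wavelengths by the
same factor is the equivalent axis convention).

# Atomic energies and scores

$E_a = Z_a^{-1} \sum_{i \in a}^{\text{valence}} \sum_j P_{ij}(H_{ij} +
\tfrac12 G_{ij})$. With normalization and the valence restriction
disabled the per-atom values sum *exactly* to the electronic energy —
the partition identity asserted on every fixture. The $1/Z_a$ factor
is the entire element-type normalization (no second standardization).
For confidence-score comparison the profile is smoothed by a
Savitzky-Golay filter along the chain (window 150 promoted to the odd
151; order 3, the filter's customary default), scaled by 15, shifted
by a structure-specific offset (user-supplied, or matched to the
score-range mean), and clipped to the score bounds.

# Gradients, optimization, dynamics

The gradient is the exact derivative of the implemented energy:
Hellmann-Feynman and Pulay one-electron terms, the full
primitive-level two-electron derivative (pair factors and the
${}_1F_1$ kernel via $F'(x) = (e^{-x} - F(x))/(2x)$), the
switching-function chain rule through the pair-center distances, and
the switched nuclear repulsion. Screening *membership* is piecewise
constant and not differentiated; the smooth switching keeps the
retained energy C1, and the task list is rebuilt at each geometry.
Agreement with central finite differences (step $10^{-4}$ bohr, max
component error $< 10^{-5}$ Ha/bohr; in practice $\sim 10^{-9}$) is
the defining test, asserted both without cut-offs and with the
switching window cutting through a water dimer.

BFGS uses inverse-Hessian updates with an energy-only golden-section
line search (initial bracket 0.5 bohr along the normalized direction,
relative interval tolerance $10^{-2}$); SCF failures inside the line
search read as $+\infty$ and shrink the interval. MD is velocity
Verlet (NVE; symplectic and second order), Maxwell-Boltzmann initial
velocities from a seed with center-of-mass motion removed, and the
total-energy drift in Ha/atom/fs as the diagnostic; halving the step
twice reduces the drift by roughly an order of magnitude.

# Synthetic fixtures and what the tests show

The fixture generators supply deterministic, download-free substrates:
idealized small molecules, rigid-geometry water clusters and shells
(r(OH) = 0.9572 Å, 104.52°; O-O ≥ 2.5 Å, heavy-atom clash ≥ 2.2 Å —
chosen to keep the SCF well-conditioned), all-trans polyenes
(1.35/1.46 Å alternation) as conjugated-chromophore stand-ins, and
extended capped polyglycine built from proper trigonal/tetrahedral
placement rules as the peptide substrate. They emulate the *geometric
and electronic regimes* of the applications — hydrogen-bond networks,
conjugation, peptide backbones — but not conformational diversity,
charged side chains, counter-ions or equilibrated solvent; green tests
on them demonstrate correctness of the machinery and the stated error
budgets, not production accuracy on real proteins.

Problem sizes throughout are chosen for a single-CPU desk workflow:
water trimer (21 basis functions) for screening convergence, C6H8 (38)
for the implementation-check protocol against a frozen independent
conventional-basis reference, capped tetraglycine (124) for the
divide-and-conquer comparison, where full HF is still cheap enough to
be its own oracle.

# Numerical choices and limitations

* Overlap eigenvalue drop tolerance $10^{-7}$; primitive pair-overlap
  floor $10^{-12}$ bounds the pair-table memory.
* Minimal basis, no correlation: binding energies are qualitative; low
  Coulomb cut-offs distort them badly (large or disabled windows are
  required for quantitative differences).
* d shells are unsupported by design; third-row tables are synthetic
  Slater-rule constructions, shipped for completeness and not
  exercised by the acceptance surface.
* No periodic boundary conditions and no Ewald-type long-range
  treatment anywhere: truncation is the model.
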