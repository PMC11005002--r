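---
title: "A multiphase liquid model of nuclear chromatin: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multiphase liquid model of nuclear chromatin: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nucphase)
```

# The model

`nucphase` treats the interphase nucleus as a set of immiscible liquids.
Every chromosomal territory is a non-conserved order parameter
$\varphi_i(\mathbf r, t) \in [0,1]$ — 1 inside the territory, 0 outside,
with a diffuse interface — and two further fields $\psi_1, \psi_2$ carry
facultative (fHC) and constitutive (cHC) heterochromatin. Euchromatin is
never stored: the chromatin-type fields obey $\sum_j \psi_j = 1$, so
$\psi_3 = 1 - \psi_1 - \psi_2$ is implicit. A static indicator
$\eta(\mathbf r)$ encodes the ellipsoidal nucleus (0 inside, 1 outside;
the envelope is its $\tfrac12$-isocontour), reflecting a fixed envelope at
interphase equilibrium; a deforming envelope is out of scope.

All fields evolve by Allen-Cahn relaxation
$\partial_t u = -L_u\, \delta F/\delta u$, with additive space-time white
noise on $\psi_1, \psi_2$ only (interface fluctuations of the finite-size
HC droplets; the slow territory fields are deterministic). The free
energy, in units of $k_BT$, is the sum of a bulk part

$$F_B = \int_\Omega \Big[ \sum_i \tfrac{\epsilon_\varphi^2}{2}
|\nabla\varphi_i|^2 + \sum_j \tfrac{\epsilon_{\psi_j}^2}{2}
|\nabla\psi_j|^2 + f(\varphi,\psi)\Big]
+ a_1\big[V_N - \sum_i V_i\big]^2 + a_2\sum_i [V_i-\bar V_i]^2
+ a_3\sum_i [v_i-\bar v_i]^2 + a_4\sum_i [w_i-\bar w_i]^2$$

with the quartic multi-well $f = \sum_i \varphi_i^2(1-\varphi_i)^2/4 +
\sum_j \psi_j^2(1-\psi_j)^2/4$, and an interaction part

$$F_I = \beta_0 \sum_i \int h(\eta)[1-h(\eta)]\,h(\varphi_i)
+ \beta_\varphi \sum_{i\neq j} \int h(\varphi_i)h(\varphi_j)
+ \beta_{\psi_1\psi_2} \int h(\psi_1)h(\psi_2)
+ \int \big[1-\sum_i h(\varphi_i)\big]\big[\beta_{\psi_1}h(\psi_1) +
\beta_{\psi_2}h(\psi_2)\big]
+ \int \nabla h(\eta)\cdot[\gamma_1 \nabla h(\psi_1) +
\gamma_2 \nabla h(\psi_2)].$$

Volumes are measured through the standard interpolant
$h(u) = u^3(10-15u+6u^2)$, which preserves the minima at 0 and 1
($h'(0)=h'(1)=0$): $V_i=\int h(\varphi_i)$, $v_i=\int h(\psi_1)h(\varphi_i)$,
$w_i=\int h(\psi_2)h(\varphi_i)$. The last term of $F_I$ is the
lamina-adhesion energy: it is negative where the $\psi$ interface overlaps
the envelope interface with aligned gradients, so $\gamma_j > 0$ rewards
heterochromatin wetting the envelope, and $\gamma_1=\gamma_2=0$ switches
adhesion off identically.

Two printed-formula ambiguities were resolved on physical grounds: the
$(1-\varphi_1)$ appearing in published renderings of $f$ is read as
$(1-\varphi_i)$ (otherwise every well except the first collapses), and the
$\psi$-gradient term is read as $|\nabla\psi_j|^2$ (a $\varphi$ subscript
there would leave the $\psi$ interfaces without interfacial energy).

## Parameters, units, defaults

Lengths are micrometers, the energy scale is $k_BT$, and time is
dimensionless: the characteristic length $l = 1\,\mu m$ and time
$\tau = 0.005$ s convert to physical units (`lengthScale`, `timeScale` in
`ModelParameters`). Defaults follow the reference Drosophila
parametrization:

| knob | default | meaning |
|------|---------|---------|
| `beta0` | 16.7 | envelope confinement of territories |
| `betaPhi` | 40 | territory-territory exclusion (large = separated CTs) |
| `betaPsi1` | 0.1 | fHC-EC coupling (HC outside territories penalty) |
| `betaPsi2` | 0 / 0.1 | cHC channel (on in the three-component preset) |
| `betaPsi12` | 0 / 4.5 | fHC-cHC exclusion (demixes the subtypes) |
| `gamma1` | 0 / 5 | fHC-lamina adhesion (adhesive preset) |
| `a1..a4` | 0.16, 2, 2, 2 | volume-constraint strengths |
| `noiseAmp` | (5, 5) | interface-fluctuation amplitudes $A_j$ |
| `dt` | 0.04 | dimensionless time step |

Interface coefficients are not free: they derive from measured chromatin
mobilities through $D = L\epsilon^2$, i.e. $\epsilon =
\sqrt{D\tau/(l^2 L)}$ (`epsilonFromDiffusion()`), with
$D_\varphi = 20\,\mu m^2/s$ and $D_{\psi} = 12\,\mu m^2/s$ and equal unit
mobilities. That gives $\epsilon_\varphi \approx 0.316$,
$\epsilon_\psi \approx 0.245$, hence diffuse interfaces of width
$2\sqrt2\,\epsilon \approx 0.7$–$0.9\,\mu m$ — deliberately thick relative
to the nucleus, which is what makes the liquid-like droplet dynamics fast
and mesh-friendly. Users who want to bypass the $D$-$L$-$\epsilon$ chain
can set `epsPhi`/`epsPsi1`/`epsPsi2` directly.

The geometry is the oblate ellipsoid $a=2.5$, $b=4$, $c=1.2\,\mu m$
centered in the $6\times9\times3\,\mu m$ box
($V_N = \tfrac43\pi abc = 50.27\,\mu m^3$), with the envelope indicator
$\eta = \tfrac12[1+\tanh((r_{ell}-1)/(2\sqrt2\,\epsilon_\eta))]$ in the
normalized ellipsoidal coordinate $r_{ell}$. Published renderings of this
profile omit the shift that puts the $\tfrac12$-level on the surface and
state the opposite sign convention in words; we follow the words (0
inside) and add the shift, which the geometry tests pin down. The eight
territory seed centers are the reference coordinates
(`defaultSeedCoordinates()`); one of them lies marginally outside the
stated ellipsoid (normalized radius 1.09), which the constructor reports
as a warning and confinement resolves within the first few time units.
Heterochromatin is seeded at each territory center with a 25% total volume
fraction; in the three-component preset the fraction is split equally
between a central cHC sphere and a concentric fHC shell, keeping
$\psi_1+\psi_2 \le 1$ by construction. Because the interfaces are thick,
seed radii are solved numerically so that the $h$-weighted profile volumes
(not the sharp-sphere volumes) meet the targets — with
$\epsilon_\psi \approx 0.245$ the naive radius would overshoot the HC
fraction by ~70%.

## Numerical scheme

The domain is a uniform Cartesian voxel grid (a deliberate re-design of
the original finite-element formulation; validated below). The discrete
free energy uses midpoint quadrature with forward-difference gradients;
its exact gradient with respect to voxel values is then the compact
7-point Laplacian with mirror (zero-flux) closure, and every coupling term
differentiates through the chain rule. This adjoint consistency is the
core correctness contract: `functionalDerivatives()` must and does match
single-voxel central finite differences of `freeEnergy()` to ~1e-8
relative, term by term.

Time stepping defaults to a stabilized semi-implicit (IMEX) scheme: the
diffusion term is treated implicitly in transform space, the nonlinear
terms explicitly with a stabilization shift $S(u^{n+1}-u^n)$. Because the
zero-flux Laplacian is diagonalized exactly by mirror extension onto a
doubled periodic grid, the implicit solve is a per-mode division under an
FFT — spectral robustness *without* giving up the zero-flux boundary
contract (periodic boundaries are also supported and use the plain FFT).
$S$ is chosen automatically each step as a sup-bound of the diagonal
nonlinear Jacobian, $\sup|f''| + \sup|h''|\cdot\max|B|$, where $B$ is the
measured coupling multiplier and the curvature suprema track the value
range the fields actually attain (both grow without bound outside
$[0,1]$, so a fixed constant is unsafe — transient overshoot once blew up
exactly this way). The stabilization slows the dynamics by the factor
$1+\Delta t\,L\,S$ (first-order consistent), which is the price of
honouring $\Delta t = 0.04$ at strong couplings; with noise off the
recorded energy is non-increasing at every step across all presets, which
the acceptance suite asserts at 1e-10 relative tolerance. An explicit
Euler scheme is retained for cross-checks; it warns outside its diffusion
stability bound $\Delta t \le h^2/(6L\epsilon^2)$. A step producing
non-finite values is retried with halved substeps a configurable number of
times before erroring with the offending step index.

Noise is discretized as independent Gaussian increments of variance
$A_j\,\Delta t/\Delta V$ per voxel (the lattice Dirac delta), applied
after the implicit solve and never projected: the soft
$\beta_{\psi_1\psi_2}$ exclusion keeps $\psi_1+\psi_2$ bounded. Note that
with this normalization the quoted amplitude $A = 5$ is extremely strong
on fine meshes (the increment scales like $\Delta V^{-1/2}$); the original
finite-element implementation evidently normalized noise differently. We
keep the stated contract and the stated amplitude as an independent
setting, but all quantitative validations run noise-off, as their
criteria specify.

## Analysis suite

Droplets are connected components (6-neighborhood) of
$\{\psi \ge 0.5\}$ — the same $\tfrac12$ level-set convention as every
interface in the model. Volumes are voxel counts times voxel volume;
surfaces are triangulated isosurfaces by marching tetrahedra (Freudenthal
6-tet cube split, edge crossings by linear interpolation) — voxel-face
counting would bias the sphericity $\Psi = \pi^{1/3}(6V)^{2/3}/S$ low by
~30%. On smooth rasterized balls at 16 voxels per radius the pipeline
reproduces $V$ within 1%, $S$ within 0.5%, and $\Psi \ge 0.97$; a cube
gives $(\pi/6)^{1/3}$ within 3%; rescaling the whole scene leaves $\Psi$
unchanged to 4 decimals. Below about five voxels across (125 voxels) the
isosurface is not meaningful and droplets report `NA` sphericity rather
than a value outside $(0,1]$. Droplet ownership is the territory whose
$h(\varphi_i)$ dominates at the centroid voxel ("shared" when the top two
are within 0.1), and a droplet "spans" the territories that dominate at
least 10% of its voxels.

Radial profiles average a field in slab bins along a named axis (major =
$y/b$, minor = $x/a$, $z/c$) inside a sampling cylinder (default radius
0.5 μm) — the 3D analogue of line profiles through the nuclear center.
Cross-chromosome centroid-distance CDFs pair droplets of the same subtype
with different owners ($j \ne i$); no smooth fit is imposed — the
empirical CDF is returned and fitting is left to the user, since the
published fit's functional form is unstated.

The morphology call uses a reproducible three-way rule with stated,
configurable thresholds (the regimes are defined qualitatively in the
literature): *disconnected-within-CT* when there are at least as many
droplets as territories and none spans two; otherwise
*connected-interior* when at least half the droplet volume has centroids
within the inner half of the normalized ellipsoidal radius; otherwise
*connected-across-boundaries*. At reduced resolution the 2×2 corner sweep
over $(\beta_\varphi, \beta_\psi) \in \{10,80\}\times\{0.1,4.5\}$
reproduces all three regimes, in the orientation the model vocabulary
implies: large $\beta_\varphi$ *separates* territories (the literature
itself calls $\beta_\varphi = 40$ "weak" chromosome interaction for
exactly this reason), so strong type coupling with separated territories
pins droplets inside chromosomes, weak coupling lets them fuse centrally,
and intermingling territories with strong coupling connect droplets
across boundaries.

## What the synthetic world does and does not establish

The generator *is* the stated world: printed coupling constants, the
printed mesh and seed coordinates, 25% HC. Reduced-resolution runs (the
acceptance suite uses 1/4 and 1/8 linear meshes) resolve the ~0.8 μm
interfaces with 3–6 voxels: adequate for energies, volumes and regime
calls, but individual droplet boundaries are coarse, so regime boundaries
in the phase diagram may shift relative to the full mesh, and small
droplets' sphericities are deliberately `NA`. The full-mesh, long-horizon
droplet-size and sphericity distributions are therefore validated by a
desk-scale surrogate instead: synthetic droplet ensembles with planted
volume modes (1.35 and 1.45 μm³) and a planted sphericity mode (prolate
spheroids of aspect ≈ 3.7, closed-form $\Psi \approx 0.8$) must be
recovered by the measurement pipeline. A green suite establishes the
machinery — energetics, dynamics, morphometry — not biological truth;
no claim is made that reduced-resolution phase boundaries sit exactly
where full-resolution ones do.

## Design choices made where the design was open

- **γ for the adhesive preset**: no printed value survives in the source
  material ("different values of γ"); we fix γ₁ = 5 once — the same order
  as the β couplings, strong enough that the peripheral shift in the
  radial profile is unambiguous at reduced resolution.
- **Three-component preset**: β_ψ1 = β_ψ2 = 0.1 (the printed weak
  HC-EC values) with β_ψ1ψ2 = 4.5, the strong subtype exclusion that
  produces the demixed fHC/cHC architecture; the HC volume is split
  equally between subtypes.
- **Ordered-pair convention**: the territory-exclusion sum over
  $i \ne j$ counts each unordered pair twice; the functional derivative
  carries the matching factor 2. Pure convention, fixed by the derivative
  oracle.
- **Configuration format**: JSON (full round-trip fidelity, no extra
  dependencies), with unknown-key rejection and preset contracts (a
  two-component preset refuses cHC or γ₂ settings).
- **Snapshots**: RDS containers (lossless, compressed) plus optional
  ASCII VTK ImageData export for external viewers; writes are atomic via
  an `.incomplete` marker that readers refuse.

## Known limitations

- The envelope is rigid; nuclear deformation, growth, and envelope
  breakdown are out of scope.
- Noise-on runs at the printed amplitude are only meaningful under the
  original (non-volumetric) noise normalization; see above.
- Droplet identity is not tracked through time (no fusion genealogy or
  coarsening exponents).
- The interface width is set by measured diffusivities, not by the true
  (unknown) chromatin surface tension; absolute energies are therefore
  model-relative.
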