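---
title: "Methods: predicting water self-diffusion under nanoconfinement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting water self-diffusion under nanoconfinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoconfine)
```

# The model

Water molecules near a solid wall feel two interactions absent in the
bulk: a van der Waals attraction/repulsion from the wall atoms and, on
charged surfaces, the interaction between the water dipole and the
electrostatic field of the partial charges. `nanoconfine` models both
along a one-dimensional profile per surface atom and condenses the
result into two scalars per structure — a characteristic confinement
length $\delta$ (nm) and a well depth $\varepsilon$ (kJ/mol) — which
then drive a linear scaling law for the self-diffusion coefficient,

$$D(\theta) = D_B\left[1 + \left(\frac{D_C}{D_B}-1\right)\theta\right],$$

with $\theta$ the fraction of the water volume within $\delta$ of
solid surfaces. The chain of assumptions:

1. **Mobility is impaired only in the near-wall layer.** Molecules
   inside the potential well of the wall (deeper than the thermal
   level, see below) are "confined"; all others diffuse like bulk.
   The average diffusivity is a mixing rule between the two
   populations, which becomes linear in $\theta$ when the confined
   and bulk water densities are comparable (`predict_D`); the
   density-weighted variant is kept as `predict_D_density`.
2. **The wall potential is pairwise additive.** $U_{\rm vdw}$ is a
   12-6 Lennard-Jones sum over all wall atoms within a cutoff, with
   Lorentz–Berthelot combination against the water-oxygen parameters
   (SPC/E values $\sigma_O = 0.3166$ nm, $\epsilon_O = 0.6502$
   kJ/mol) unless the parameter table already stores combined values
   (`precombined` flag).
3. **The dipole responds thermally, not mechanically.** The Coulomb
   term is the Boltzmann orientation average of $-\mu E\cos\phi$,
   $U_c = -\mu_w E\,\Gamma(\mu_w E/k_BT)$ with the Langevin function
   $\Gamma(x) = \coth x - 1/x$ and the SPC/E dipole moment
   $\mu_w = 7.50\times10^{-30}$ C·m. Water's own screening enters
   through a distance-dependent relative permittivity.
4. **Escape is a thermal-energy criterion.** A molecule at distance
   $n$ from the surface atom is confined when
   $U_{\rm eff}(n) < -\alpha k_B T$. The two zeros of
   $U_{\rm eff}(n)+\alpha k_BT$ bracketing the well minimum give
   $\delta_i = n_2 - n_1$; when the thermal line misses the well,
   $\delta_i = 0$. For planar walls $\alpha = 1/4$: half of the
   $k_BT/2$ kinetic energy of the single escape degree of freedom,
   since escape is possible only through the outward half-space.
5. **Surface averaging is area-weighted.**
   $\delta = \sum_i \delta_i S_{{\rm loc},i}/S_{\rm tot}$ over the
   solvent-accessible surface; buried atoms have
   $S_{{\rm loc},i} = 0$ and drop out automatically. The same
   weighting defines `epsilon_mean`, the energy scale handed to the
   supercooled-water route.

## Geometry: SAS and normals

The solvent-accessible surface is computed by Shrake–Rupley point
sampling on a deterministic golden-spiral point set. The atomic radius
is $\sigma_k/2$ — the only per-atom length the force-field parameters
provide — plus a probe radius of 0.14 nm (a water-sized probe); both
are configurable, and neither choice is sharp: $\delta$ responds to
them only through the selection of exposed atoms and the direction of
their normals. The outward normal of atom $i$ is the unit vector from
the atom centre through the centroid of its accessible points, which
realizes "orthogonal to the SAS through the atom centre" without
meshing a surface. With 960 points per atom the sphere-closure error
of an isolated atom is below 1 %. Rotating a structure changes which
sample points are occluded, so SAS values are rotation-invariant only
to the sampling resolution (about $2/\sqrt{n}$ relative), not exactly;
translation invariance is exact.

## From $\delta$ to $\theta$

$V_{\rm in} \approx \sum_p S^{(p)}_{\rm tot}\delta^{(p)}$ is exact for
planes; for curved walls the package uses exact shell volumes
(`sphere`, `cylinder_inner` with $\delta$ capped at the pore radius,
`cylinder_outer`), which reduce to $S\delta$ at small $\delta/R$.
Overlapping volumes of influence — several particles in a pore — are
not additive; under the continuum-percolation assumption of randomly
placed volumes the effective fraction is $1-\exp(-\theta)$. The
correction is auto-enabled when a scene holds more than one surface
copy and can be forced either way. $\theta$ is clamped to $[0,1]$ at
the end of the pipeline (the domain of the law); the raw apparent
value is preserved for diagnostics. An uncertainty on the water number
density $\rho_n$ propagates to a $\theta$ error bar by finite
difference through the correction.

## The fully confined diffusivity

Confined water is treated as supercooled bulk water: losing energy
$\varepsilon$ to the wall well is equivalent to cooling by
$f^{-1}(-\varepsilon)$, where $f(T)=\int_{T_0}^{T}c_p\,dT$ with
$f(T_0)=0$ at $T_0=300$ K, and the diffusivity ratio of supercooled
water $g(T)$ evaluated there gives $D_C/D_B$. The unit bridge is
explicit: $\varepsilon$ (kJ/mol per molecule) is converted to J/kg via
the molar mass of water before entering $f^{-1}$ — the bookkeeping is
a design decision of this package and is tested against closed forms.
Whether the per-structure well depth should be the SAS-weighted mean
or the maximum is genuinely open; both (`epsilon_mean`,
`epsilon_max`) are returned and the mean is the default, since the
same surface average defines $\delta$. Experimental $c_p(T)$ and
$g(T)$ curves are *not* bundled: users supply two-column tables, and
`synthetic_thermo_tables()` provides a clearly synthetic stand-in — a
$c_p$ curve with a supercooled-water-like peak near 225 K and a
Vogel–Fulcher–Tammann ratio $g(T)=\exp(-B/(T-T_{\rm VFT})+
B/(T_0-T_{\rm VFT}))$ with $B = 900$ K, $T_{\rm VFT} = 175$ K, chosen
once so that wells of a few kJ/mol map to $D_C/D_B \lesssim 0.15$,
the regime reported for silica-like surfaces.

# Numerical choices

* **Profile grid**: $n \in [0.05, 1.0]$ nm, 2000 uniform points; the
  neighbour cutoff (1.0 nm default) doubles as the outer grid end.
  Halving the grid step changes $\delta$ on the slab fixture by less
  than 0.5 %, and the tests assert this.
* **Root refinement**: crossings of $U_{\rm eff}+\alpha k_BT$ are
  refined by `uniroot` (tolerance $10^{-9}$ nm) on the exact profile
  evaluator when available, else on a cubic spline through the grid;
  the parabolic-well closed form is recovered to $10^{-6}$ nm either
  way.
* **Multiple sign structure**: when charges carve secondary minima,
  $n_1$ and $n_2$ are the innermost and outermost crossings that
  bracket the *global* minimum — the conservative (largest) trapped
  region. A single well reduces to "the two zeros".
* **Coincident grid points**: distances to wall atoms are floored at
  $10^{-4}$ nm with a logged message, so pathological normals cannot
  produce infinities.
* **Permittivity**: $\epsilon_r(r)$ defaults to a sigmoid rising from
  1 at contact to 78 in the bulk (midpoint 0.35 nm, width 0.07 nm) —
  interfacial water screens poorly; a constant-$\epsilon_r$ model
  exists for oracle tests. The sigmoid parameters are a package
  choice; the qualitative requirement is only the 1-to-78 rise over
  the first hydration shells.
* **Langevin function**: series $x/3 - x^3/45$ below $10^{-3}$ to
  avoid cancellation; the branches agree to $10^{-9}$ at the
  switchover.
* **MSD**: FFT autocorrelation algorithm, asserted equal to the naive
  double loop on small cases; default fit window 10–50 % of the
  maximum lag (short lags excluded as ballistic/caging-like, long
  lags as noise-dominated; the literature rarely states its window).
  Standard errors come from the spread of per-particle slopes, which
  are independent, rather than from OLS residuals, which are not.
* **Degenerate inputs**: empty structures, zero-area surfaces,
  overfilled pores, wrapped trajectories, all-zero images and
  out-of-range temperatures raise explicit errors rather than
  propagating NaNs.

# Synthetic generators: what they emulate

All fixtures are generated in code; nothing is downloaded.

* **Lattice builders** (`build_sphere`, `build_cylindrical_pore`,
  `build_planar_slab`) place atoms on simple-cubic lattices. They
  emulate the *geometry* of hydroxylated nanoparticles, silica pores
  and flat walls, not their crystallography: the $\delta$ algorithm
  consumes only positions and parameters, so crystal fidelity buys
  nothing for these tests. Consequently the absolute $\delta$ of a
  real SiO₂ or Fe₃O₄ structure is not reproduced by the fixtures —
  only the behaviour of the algorithm on controlled geometry.
* **`build_cnt`** is exact for armchair tubes: carbons on a rolled
  honeycomb lattice with 0.142-nm bonds, neutral, with the combined
  carbon–water LJ parameters ($\sigma = 0.36$ nm, $\epsilon = 0.29$
  kJ/mol). Chiral and zigzag tubes are out of scope.
* **`generate_brownian`** produces ideal normal diffusion (Gaussian
  steps of variance $2D\,dt$ per axis). Real MD water shows ballistic
  and caging regimes at short times; the default fit window excludes
  short lags for that reason, but passing the recovery tests says
  nothing about force-field accuracy.
* **`generate_synthetic_edx`** drops Gaussian intensity blobs
  (trimmed to true zeros at 0.1 % of their peak) on a raster, with
  defaults chosen once for a 1000-nm construct with 40-nm pores:
  64×64 pixels of 15.6 nm, 25 clusters, 20 000 SPIOs of 2.5-nm core
  radius, pore fill fraction 0.2. It emulates clustering statistics,
  not instrument physics (no beam spread, no noise floor, no Si-wall
  signal). The enhancement average of a synthetic scene is therefore
  a property of these choices, not a prediction for any real
  construct.

# The relaxivity chain

The mapper carries a label image to an enhancement map in five
mass-conserving steps: pixel density (normalized so
$\sum\rho\,A_{\rm pix}=N_{\rm SPIO}$), pore-scale smoothing of the
labelled-pixel indicator (Gaussian kernel, bandwidth one pore
diameter in pixels — the pixel scale is not physically meaningful),
re-normalization by mass conservation, a representative-pore $\theta$
(spherical shells around each SPIO, percolation-corrected, against
the filled pore volume), and a linear calibration
$\theta(X,Y)=C'\rho_{\rm SPIO}(X,Y)$ with $C'$ fixed by requiring the
$\rho$-weighted mean over occupied pixels to equal the
representative-pore value. Values clamp to $[0,1]$ and the clamped
mass fraction is reported. The representative pore receives the
density-weighted mean occupancy $\bar\rho = \sum\rho^2/\sum\rho \cdot
A_p$ — the occupancy an average *SPIO* experiences, which is the
relevant weighting for relaxation. The local volume-fraction map is
$\upsilon = \rho_{\rm SPIO}V_{\rm SPIO}/(h\,c_{\rm fill})$, and the
bulk reference $\upsilon_B$ defaults to the same SPIOs spread over
the whole construct volume. Only the enhancement *ratio*
$En=(\upsilon/D)/(\upsilon_B/D_B)$ is computed — the absolute
outer-sphere $r_2$ prefactor cancels in it, and the definitional
$r_2=(1/T_2-1/T_{0,w})/M_{\rm Fe}$ is provided for measured times.

# Test problem sizes

The suite exercises: slabs of 50–108 atoms (potential stage), dimers
and triatomics against $10^6$-point Monte-Carlo SAS oracles, a
1000-particle × $10^4$-frame Brownian fixture plus twenty
100 × 2000 replicates for bias and coverage, 60-point noisy fits, and
48×48 synthetic scenes. These sizes were chosen to give each
statistical assertion comfortable power while keeping the default
test run fast.

# Known limitations

* Long-range electrostatics are truncated at the neighbour cutoff; no
  Ewald summation. Highly charged periodic surfaces will be
  under-screened.
* The percolation correction assumes randomly placed volumes of
  influence; ordered arrays of particles violate it.
* $\alpha = 1/4$ is exact only for planar escape; curvature-specific
  $\alpha$ is left to the user.
* The MSD unwrapping cannot recover frame-to-frame displacements
  larger than half the box (aliasing).
* Protein structures are ingested as-is: no protonation logic, and
  the parameter table must resolve every atom name.
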