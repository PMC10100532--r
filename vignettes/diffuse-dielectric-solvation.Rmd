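---
title: "Diffuse-boundary continuum solvation with gpes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffuse-boundary continuum solvation with gpes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpes)
```

## The model

`gpes` computes the electrostatic solute–solvent interaction of an
implicit-solvent model in which the solvent is a structureless
dielectric with a *position-dependent* permittivity. Instead of the
sharp cavity surface of apparent-surface-charge continuum models
(PCM/IEFPCM), the boundary between solute and solvent is a smooth shell
of finite width, so the governing equation is the generalized Poisson
equation (GPE, Gaussian units)

$$\nabla\cdot\left[\varepsilon(\mathbf r)\,\nabla V(\mathbf r)\right]
  = -4\pi\rho(\mathbf r),$$

with no boundary conditions on any interior surface. Two classical
assumptions of sharp-cavity models — all solute charge strictly inside
the cavity, and a permittivity jump across a 2-D surface — are thereby
relaxed: charge that leaks outside the cavity ("escaped charge") is
polarized by the full volume of the dielectric automatically.

### Cavity and permittivity

The cavity is a union of atom-centered spheres. Each sphere gets an
effective radius

$$R_i = \alpha\,R_i^{\mathrm{vdW}} + \beta\,\sigma,$$

from the Bondi van der Waals radius, a dimensionless scale $\alpha$, a
width-proportional offset $\beta\sigma$, and the boundary width
$\sigma$ (bohr). The defaults $\alpha = 1.1$, $\beta = 0.5$, $\sigma =
0.2$ au are the parametrization found to correlate well with
sharp-cavity reference calculations for neutral solutes across
permittivities 2–80; $\beta = 0$ reproduces plain scaled-Bondi radii.
With the signed distance $s_i(\mathbf r) = |\mathbf r - \mathbf r_i| -
R_i$, each sphere carries the smoothed indicator

$$C_i(\mathbf r) = \tfrac12\,\mathrm{erfc}\!\left(\frac{s_i}{\sigma}\right),$$

which tends to the Heaviside step as $\sigma \to 0$. The molecular
cavity function is the complement product

$$C(\mathbf r) = 1 - \prod_i\bigl(1 - C_i(\mathbf r)\bigr),$$

which equals $C_1$ for a single sphere, is 1 deep inside any sphere and
0 far outside all of them. (A direct product of the $C_i$ would vanish
inside a sphere that lies outside another, so the complement product is
the only combination consistent with an interlocking-spheres union;
both the sigmoid profile and this combination rule are isolated behind
single functions so an alternative is a one-line change.) The
permittivity interpolates exponentially,

$$\varepsilon(\mathbf r) = \varepsilon_{\mathrm{in}}
  \exp\!\left[(1 - C(\mathbf r))\,
  \ln\frac{\varepsilon_{\mathrm{out}}}{\varepsilon_{\mathrm{in}}}\right],$$

i.e. log-linear in $1 - C$; the direction is fixed by the physical
setup (vacuum-like $\varepsilon_{\mathrm{in}} = 1$ inside, bulk solvent
outside). The exponential form makes the log-derivative a pure cavity
quantity,

$$\nabla\ln\varepsilon = -\ln\!\left(
  \varepsilon_{\mathrm{out}}/\varepsilon_{\mathrm{in}}\right)\nabla C,$$

and $\nabla C$ has a closed form by the product rule, so no numerical
differentiation of $\varepsilon$ is needed.

### SCRF iteration

Rewriting the GPE in Laplacian form splits the source into the
effective charge $\rho_{\mathrm{eff}} = \rho/\varepsilon$ and the
polarization function

$$\gamma(\mathbf r) = \frac{1}{4\pi}\,\nabla\ln\varepsilon\cdot\nabla V,$$

giving, after subtracting the vacuum part $V_\rho$ (with $\nabla^2
V_\rho = -4\pi\rho$), a fixed-point equation for the reaction potential
$V_R = V - V_\rho$:

$$V_R = \hat P\left[(\rho_{\mathrm{eff}} - \rho) + \gamma(V_\rho + V_R)\right],
\qquad \hat P[f](\mathbf r) = \int\frac{f(\mathbf r')}{|\mathbf r -
\mathbf r'|}\,d^3r'.$$

Because $\gamma$ depends on the total potential, the equation is solved
by microiterations: assemble $V = V_\rho + V_R^{(i)}$, evaluate
$\gamma$, apply the free-space Poisson kernel, and take an accelerated
update. Convergence is checked on the $L^2$ field norm of the accepted
reaction-potential update against a threshold $\delta$. The
polarization energy is the linear-response charging work

$$E_{\mathrm{pol}} = \tfrac12 \langle\rho,\,V_R\rangle ,$$

whose $\tfrac12$ prefactor is fixed by the linearity of $V_R[\rho]$ and
by the requirement that the sharp-cavity limit reproduce the Born
closed form $-\tfrac12(1 - 1/\varepsilon)q^2/R$.

### KAIN acceleration and the macroiteration regimes

The plain fixed-point iteration is not reliably contractive: at
$\varepsilon_{\mathrm{out}} = 80$ the update norms of the undamped
iteration *grow* by roughly 16% per step for a Born sphere. The
Krylov-accelerated inexact Newton (KAIN) scheme — a DIIS/Anderson-type
history method — restores and accelerates convergence: with the default
history length $N = 5$ the Born systems here converge in 9–14
microiterations. On an exactly linear map KAIN is Krylov-exact: a
5-dimensional toy fixed-point problem converges in 6 steps with full
history, against hundreds of plain steps at the same contraction rate.
A damping factor for the plain step is exposed (`damping`, default 1)
for pathological contrasts.

In production use the reaction-field solve is nested inside an outer
self-consistent-field (SCF) loop whose density converges across
*macroiterations*. `macro_driver()` emulates this with a prescribed
density sequence and implements the four regimes formed by two
switches: the starting guess for $V_R$ (**A** zero each macroiteration,
**B** the previous converged $V_R$) and the microiteration threshold
(**C** fixed at the target $\delta$, **D** dynamic, set to the parent
density-update norm). The dynamic threshold is floored at the target
$\delta$ so the final solve always reaches full precision, and the
first macroiteration (which has no parent update) runs at the target
threshold, so all regimes coincide on a single-entry sequence. **BD**
is the default: thresholds tighten exactly as the warm start improves.
On an 8-step geometric charge ramp the totals here order as
BD $\le$ AD $\le$ BC $\approx$ AC (37 vs 56 vs 71 vs 72
microiterations on the small Born test system).

## Discretization

The original formulation of this model lives in an adaptive
multiresolution (multiwavelet) basis; `gpes` replaces that machinery by
a uniform Cartesian grid with explicit accuracy contracts, which keeps
every operation transparent and testable in plain R:

* **Box construction.** Axis-aligned bounding box of all cavity
  spheres extended by `padding` (default 8 bohr), snapped to the grid.
  Because the Poisson kernel is applied as a *free-space* convolution
  on a zero-padded (doubled, rounded to 7-smooth FFT sizes) grid, there
  is no boundary-condition error at the box faces; the padding mainly
  ensures the density and the boundary shell lie well inside the box.
* **Kernel quadrature.** Midpoint collocation of the $1/r$ kernel is
  second-order accurate with two localized defects: the singular self
  cell and the near-singular neighbor cells. The default `"refined"`
  operator uses the exact cubic-cell average for the self cell
  (constant $2.3800774/h$), exact cell averages for the $5^3$
  neighborhood, and folds the midpoint endpoint correction $\rho -
  (h^2/24)\nabla^2_h\rho$ into the kernel symbol; the result is
  accurate to $3.7\times10^{-5}$ (relative, max over the interior) for
  a Gaussian of width $w = 4h$, converging at roughly fourth order. The
  `"collocation"` operator is the plain midpoint sum with the
  equivalent-volume-sphere self term, matching the brute-force
  `direct_sum_oracle()` to rounding error — that pairing validates the
  FFT path itself, while the closed-form Gaussian potential validates
  the refined quadrature.
* **Boundary-shell sampling.** The solver samples
  $\nabla\ln\varepsilon$ from the *radially cell-averaged* profile
  derivative $(C(s + h/2) - C(s - h/2))/h$ rather than the pointwise
  one. The two agree to $O(h^2)$ for resolved shells, but the averaged
  form keeps the integrated boundary charge exact even when $\sigma
  \lesssim h$, which removes most of the thin-shell energy bias. The
  exported `cavity_gradient()` defaults to the pointwise closed form
  (and is verified against finite differences of the cavity function);
  the cell average is an explicit option.
* **Resolution contract.** The remaining discretization error is
  controlled by two ratios: $w \ge 2h$ for Gaussian charges (enforced)
  and $\sigma \gtrsim 2h$ for the boundary shell (recommended). With
  $\sigma = 2h$ the Born energies reproduce the exact continuum values
  of the model to better than 0.5%; at $\sigma = h/2$ the bias on
  $|E_{\mathrm{pol}}|$ is several percent. The a-posteriori
  `gpe_residual()` is dominated by the finite-difference truncation of
  the exponential shell ($\varepsilon$ changes by a factor
  $e^{\ln(80)h/(\sigma\sqrt\pi)}$ per cell) and is therefore a
  convergence-rate diagnostic, not an absolute error bound; the sharper
  solution check is the independent sparse finite-difference solve
  (`solve_gpe_fd()`, flux-form 7-point stencil with face-sampled
  permittivity and screened multipole Dirichlet faces), which agrees
  with the SCRF potential to $<10^{-2}$ relative $L^2$ on a resolved
  $32^3$ system.

### The exact diffuse-Born oracle

For a point charge centered in a single smoothed sphere the GPE is
radial and Gauss's law gives the exact answer by quadrature:

$$E_{\mathrm{pol}}^{\mathrm{exact}}(\sigma) =
 -\frac{q^2}{2}\int_0^\infty \frac{1 - 1/\varepsilon(r)}{r^2}\,dr .$$

`born_exact_diffuse()` evaluates this and separates *model* error
(diffuse vs sharp boundary) from *discretization* error. Two
consequences worth knowing:

* The erfc/exponential model converges to the sharp Born value roughly
  linearly in $\sigma$, but with a sizable constant driven by
  $\ln\varepsilon_{\mathrm{out}}$: at $R = 3$, $\varepsilon = 80$ the
  exact deviations from Born are 11.1% ($\sigma=0.4$), 5.1%
  ($\sigma=0.2$), 2.4% ($\sigma=0.1$), 1.2% ($\sigma=0.05$). The
  exponential interpolation makes $\varepsilon$ rise quickly on the
  *inner* flank of the shell (at $s = -\sigma$ already $\varepsilon
  \approx 1.4$), so the effective cavity is slightly smaller than $R$
  and diffuse-boundary energies overshoot the sharp Born magnitude.
* Sub-$h$ shells cannot be represented on a uniform grid: resolving
  $\sigma = 0.05$ bohr needs $h \approx 0.025$ bohr, i.e. $>400^3$
  nodes for a padded Born box, beyond what this plain-R implementation
  targets. The test suite therefore demonstrates sharp-limit
  convergence of the *model* with the exact oracle, and solver accuracy
  at resolved widths.

## Synthetic solute densities

There is no quantum-chemistry engine here: solute densities are sums of
atom-centered normalized Gaussians, $\rho(\mathbf r) = \sum_i q_i(\pi
w_i^2)^{-3/2} e^{-|\mathbf r - \mathbf r_i|^2/w_i^2}$. By default an
atom carries its formal nuclear charge (an XYZ file's optional 5th
column supplies partial charges instead, e.g. TIP3P water), and the
default width 0.4 bohr is resolvable at the default 0.2 bohr spacing
while keeping $>99.9\%$ of each atom's charge inside a 1.1-scaled Bondi
sphere. What this emulates — and what it does not: the densities are
smooth, integrable and partially "escape" the cavity like a real
electronic density's tail, so volume polarization is exercised; but
there is no self-consistent response of the solute to the reaction
field (the density is frozen), no exchange–correlation or kinetic
contribution, and no nuclear-point-charge cusps. Passing tests
demonstrate the electrostatic solver, not chemistry: absolute energies
for bare-nuclei molecules are not comparable to any experimental
solvation energy, which is why the verification battery is built from
closed forms (Born, Onsager, Gaussian potentials) and independent
numerical oracles instead.

## Numerical choices and degenerate inputs

* All internal quantities are in Hartree atomic units; conversions only
  at I/O boundaries (XYZ in angstrom by default, cube files in au).
* Convergence norm: $L^2$ field norm ($\sqrt{h^3\sum f^2}$) of the
  accepted update, threshold `delta` default $10^{-5}$.
* KAIN's small linear system is solved directly; a singular history
  matrix falls back by evicting the oldest pair (duplicated iterates
  degrade gracefully to the plain step).
* At an exact sphere center the radial direction is undefined; the
  gradient contribution is set to zero (removable: the profile
  derivative is $e^{-(R/\sigma)^2}$ there).
* A homogeneous model ($\varepsilon_{\mathrm{out}} =
  \varepsilon_{\mathrm{in}}$) exits after one microiteration with
  $V_R \equiv 0$ exactly.
* Non-convergence raises a classed condition
  (`gpes_scrf_error`) carrying the full update-norm trace.
* Charge density significant at the box faces triggers a truncation
  warning; `direct_sum_oracle()` refuses grids beyond $32^3$ and
  `solve_gpe_fd()` beyond $40^3$ (cost guards).

## Problem sizes used in the shipped checks

The test battery and the acceptance script run Born spheres between
$32^3$ and $111^3$ nodes, a $97^3$ four-point $\sigma$ sweep, $49^3$
kernel-accuracy grids, $24^3$ brute-force comparisons, and one
default-parameter water molecule at about $114^3$ nodes — sizes chosen
so each check isolates one error source at a resolution where its
contract is meaningful.

## Known limitations

* Uniform isotropic grids only: no adaptivity, non-orthogonal cells or
  periodic boundaries; memory grows as the padded box cube.
* Isotropic scalar permittivity only (no tensor media, no
  cavity-independent profiles such as droplets or membranes).
* Sub-grid boundary widths ($\sigma < h$) carry a documented
  percent-level energy bias; resolve the shell instead.
* Frozen classical densities; coupling to a live SCF driver is
  emulated by `macro_driver()`, not implemented against a quantum code.
* Total solvation free energies (cavitation, dispersion, repulsion) are
  out of scope; `E_pol` is the electrostatic polarization term only.
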