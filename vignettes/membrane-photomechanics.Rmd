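---
title: "Methods: membrane mechanics and electrostatics of photoswitchable lipid vesicles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: membrane mechanics and electrostatics of photoswitchable lipid vesicles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photomem)
```

photomem analyses the light response of lipid membranes doped with
azobenzene photolipids (azo-PC): UV light (365 nm) isomerizes the
azobenzene in the acyl chain from *trans* to the bent *cis* form, blue
light (465 nm) reverses it, and the isomerization changes the membrane's
area per lipid, thickness, bending rigidity, capacitance and dielectric
constant. This vignette documents the models behind each estimator, the
tunable parameters, what the synthetic generators do and do not emulate,
and the numerical choices that were genuinely open.

## Flicker spectroscopy

A quasi-spherical vesicle of mean radius $R$ with bending rigidity
$\kappa$ and tension $\sigma$ fluctuates thermally. Expanding the shape in
orthonormal spherical harmonics, the amplitude variances are

$$\langle |u_{lm}|^2 \rangle = \frac{k_BT}{\kappa\,(l-1)(l+2)\,[l(l+1)+\bar\sigma]},
\qquad \bar\sigma = \frac{\sigma R^2}{\kappa}.$$

Microscopy sees only the equatorial cross-section, so the observable is
the Fourier spectrum of the relative radial displacement
$u(\phi) = (r(\phi)-R)/R$, with the one-sided coefficient convention
$u_q = \frac{1}{2\pi}\int u\,e^{-iq\phi}\,d\phi$ (a perturbation
$\varepsilon\cos 3\phi$ therefore carries $\varepsilon^2/4$ in mode 3).
Projecting the harmonics onto the equator gives the model fitted by
`fit_helfrich()`:

$$\langle |u_q|^2 \rangle = \frac{k_BT}{\kappa} \sum_{l\ge q}
\frac{N_{lq}}{(l-1)(l+2)\,[l(l+1)+\bar\sigma]},
\qquad N_{lq} = \frac{2l+1}{4\pi}\frac{(l-q)!}{(l+q)!}\left[P_l^q(0)\right]^2,$$

nonzero only for even $l+q$. Design choices:

* **Full Legendre sum, not the planar approximation.** The planar
  $q^{-3}$ form is the large-$q$ limit (the model's log-log slope over
  $q \in [10,30]$ is $-3.0$, which the tests check); at the crossover
  modes 3–5 that carry the tension information the full sum differs
  appreciably, so we fit it directly. The sum is evaluated in log-space
  through `lgamma` to stay finite at large $l$.
* **Truncation.** The sum is cut at `l_max = 4 * q_max`. The obvious
  choice of twice the largest mode leaves a 3–5% deficit at the top of
  the fit range (the tail falls off only as $l^{-3}$); quadrupling keeps
  the truncation below 1% for every mode, verified in the tests by
  doubling `l_max` again.
* **Fit parameterization.** The model is linear in $k_BT/\kappa$ at
  fixed $\bar\sigma$, so the fit profiles the rigidity analytically and
  minimizes over a single parameter, $\log\bar\sigma$, on
  $[10^{-6}, 10^8]$. A solution pinned at either bound is flagged and
  treated as a quality-control failure. Weights are $1/\mathrm{SE}^2$
  with standard errors taken across frames; parameter covariances come
  from the weighted Jacobian.
* **Fit range.** `q_min = 3` by default — the lowest modes are dominated
  by tension and by slow shape modes — and `q_max = n_points/8`, well
  inside the reported range `n_points/4`, so detection noise at high
  modes does not enter the fit.
* **No motion-blur correction.** The estimator assumes exposure times
  short enough (hundreds of microseconds) that mode amplitudes do not
  average within a frame; the generator is consistent by construction.

Quality control (`qc_filter()`) accepts defect-free vesicles with
$R \in [10, 25]\,\mu$m and fitted tension in $[10^{-9}, 10^{-7}]$ N/m,
the windows in which quasi-sphericity and the low-tension spectrum model
hold. Absolute rigidities for real membrane compositions require the
original video data; what the package validates is recovery of known
generator parameters, at the composition extremes reported for azo-PC
membranes (about 5 $k_BT$ for pure *cis*, about 70 $k_BT$ for pure
*trans*).

### The contour generator

`sim_flicker_contours()` draws, per frame, independent complex Gaussian
mode amplitudes whose variances equal the model above (modes 2 to
`n_points/2 - 1`, so the sampled contour has no aliased power), inverts
the transform, and adds radial pixel noise if requested. Two deliberate
simplifications: mode amplitudes are independent **between frames** (the
estimator uses only per-mode variances; temporal correlation changes
effective sample sizes on real data but not the expectation), and pixel
noise defaults to zero (it adds a white floor $\propto
\mathrm{SD}^2/n$ per mode that a real analysis would subtract or avoid
by limiting `q_max`). Passing the recovery tests therefore demonstrates
correctness of the spectral chain, not robustness to correlated detection
artefacts of real video microscopy.

## Electrodeformation

In an AC field a vesicle with higher internal conductivity deforms into a
prolate spheroid with semi-axis $a$ along the field; both semi-axes are
visible in the microscope, so the area follows from the closed form
$A = 2\pi b\,(b + a \arcsin\varepsilon/\varepsilon)$ with
$\varepsilon^2 = 1-(b/a)^2$. For $\varepsilon < 10^{-4}$ the series
$1+\varepsilon^2/6+3\varepsilon^4/40$ avoids the $0/0$; the tests pin the
formula against surface-of-revolution quadrature to $10^{-9}$ relative
over $a/b \in (1, 10]$. Oblate inputs are **rejected** by default — the
area protocol guarantees prolates, and silently applying the oblate
formula would hide a data problem — with `allow_oblate = TRUE` available
for frequency-sweep morphologies.

Photoswitching kinetics are exponential relaxations of the aspect ratio.
`fit_relaxation()` fits $a/b(t) = \text{baseline} + B\,e^{-(t-t_0)/\tau}$
with $t_0$ **fixed to the epoch start**: illumination switches stepwise,
and floating $t_0$ correlates strongly with $\tau$. The amplitude is
signed, covering the UV rise and the blue-light decay with one form; an
amplitude indistinguishable from zero (within twice its standard error)
is flagged flat rather than reported as a spurious time constant.
Reversibility statistics use the classical one-way ANOVA
(`anova_oneway()`, equal-variance F test); identical degenerate groups
return $F = 0$, $p = 1$.

## Specific membrane capacitance

With conductivity ratio $\Lambda = \lambda_{in}/\lambda_{out} < 1$ the
vesicle is prolate at low frequency and oblate at high frequency; the
aspect ratio crosses 1 at

$$f_c = \frac{\lambda_{in}}{2\pi R C_m}\,\big[(1-\Lambda)(3+\Lambda)\big]^{-1/2}.$$

Typeset renderings of this relation are easy to misread, so the exponent
lives in one named constant in the code and the adopted form is checked
against the downstream capacitance and dielectric numbers it must
reproduce. Detection interpolates the crossing linearly in
$\log_{10} f$ (sweeps are log-spaced over 500 Hz–1 MHz) after a 3-point
running median; if several crossings survive, the lowest-frequency one is
returned with a warning rather than an error, since low-frequency
crossings precede electrokinetic artefacts. $C_m$ comes from the slope of
$f_c$ versus $1/R$ over ten vesicles (free intercept; the model predicts
zero intercept and leaving it free makes the check honest).

The measured $C_m$ is the series combination of the bare bilayer and the
two diffuse double layers, $1/C_m = 1/C_B + 1/C_{D,in} + 1/C_{D,out}$
with $C_D = \varepsilon_{r,W}\varepsilon_0/\lambda_D$ and Debye length
$\lambda_D = \sqrt{\varepsilon_{r,W}\varepsilon_0 k_BT / (2 N_A e^2 c)}$;
finally $\varepsilon_{r,B} = C_B d/\varepsilon_0$ with the AFM thickness
$d$. Defaults: 296 K (room temperature, 23 °C),
$\varepsilon_{r,W} = 80$, $\varepsilon_0 = 8.8541878128\times10^{-12}$
F/m. Note that chaining the *mean* printed inputs gives dielectric
constants a few percent away from averages taken per vesicle; the
package reports the chain value and leaves averaging strategy to the
caller.

The sweep generator uses a tanh profile in log-frequency (amplitude 0.35,
width 0.4 decades) crossing 1 exactly at the model $f_c$. Only the
crossing location is physical; the profile shape is cosmetic, which is
precisely why the analysis extracts nothing but the crossing.

## AFM bilayer thickness

Height maps of supported-bilayer patches on glass are processed as: (i)
per fast-scan line, a first-order polynomial is fitted and subtracted,
excluding patch pixels by iterative **one-sided** rejection — refit after
discarding pixels more than 1 nm above the first fit, refit again after
discarding pixels more than 0.5 nm above the second (patches protrude
upward; symmetric rejection would eat the substrate) — falling back to
the previous pass with a warning if fewer than 4 pixels survive; (ii) a
10×10 pixel moving average (shrunken windows at the edges, so constants
are preserved); (iii) a height histogram of a patch-containing crop whose
two most prominent local maxima, at least 1 nm apart, are the substrate
and patch levels; their distance is the bilayer thickness.

Open numerical choices, all exposed as arguments: bin width 0.05 nm
(resolves the 0.3–0.4 nm spread of real patch heights while keeping
Poisson noise per bin manageable); 1 nm minimum peak separation
(excludes roughness side-lobes, passes any physical bilayer); peak
position by parabolic interpolation around the histogram mode (a local
Gaussian fit is available but adds assumptions); a third peak within 20%
of the patch peak's prominence raises an ambiguity error instead of a
guess. Histogram breaks are aligned so the lowest height sits at a bin
centre, which makes noiseless two-level maps exact. The fast-scan axis is
taken to be CSV rows; transpose the matrix for the other convention.

The generator (`sim_height_map()`) is tilt + step $\times$ mask +
Gaussian roughness. It does not emulate scanner bow (second-order
background), tip convolution at patch edges, or streak noise; the
recovery results certify the flatten/smooth/histogram chain, not those
instrument artefacts.

## Elasticity bookkeeping

The stretching modulus is fitted from tension versus area-per-lipid
points, $\Sigma = K_A (A - A_0)/A_0$, in the equivalent linear-in-$A$
form ($K_A$ = minus the intercept, $A_0$ from intercept over slope):
identical optimum, no nonlinear optimization, and well-conditioned for
the narrow strain ranges (1–8%) that bilayer simulations sample. The
interleaflet coupling constant follows from $\kappa/K = \beta d^2$ as
$1/\beta = K d^2/\kappa$ — 12 for rigidly coupled leaflets, 24 for the
polymer-brush prediction, 48 for freely sliding monolayers. Volume
conservation of the stretched sheet links an area increase
$\alpha = \Delta A/A$ to thinning $\Delta d/d_0 = \alpha/(1+\alpha)$: a
20–30% photo-induced area gain implies a 17–23% thickness loss, of order
1.1–1.5 nm for a 6.2 nm bilayer. One sign convention is worth stating
explicitly: `monolayer_expansion()` reports the *trans*-to-*cis* area
change as positive ( $100\,(A_{cis}-A_{trans})/A_{trans}$ ), so expansion
is positive and reverse switching negative; all percent outputs in the
package are signed, never silently absolute-valued.

## Contour detection from images

`detect_contour()` stands in for lab-internal contour software: rays are
cast from the intensity centroid of the inverted image (or a caller
hint), the dark ring is localized on each ray as the minimum of the
lightly smoothed radial profile with parabolic sub-pixel refinement, and
the centre is iterated with the contour centroid until it moves less than
0.1 pixel. The edge is defined as the radial intensity **minimum** — the
phase-contrast appearance of a vesicle with sugar asymmetry is a dark
ring on a light background — not the maximum gradient; switching
definitions is a one-line change of the profile score. Detection is
invariant to affine intensity rescaling. Failure modes are explicit: no
ray with sufficient contrast ("no edge found"), more than 5% of rays
failing ("open contour"), or a majority of rays seeing two comparable
minima without a centre hint ("ambiguous contour"; with a hint, the
candidate nearest the consensus radius is chosen). Recovery on rendered
images is better than 0.1 pixel in mean radius and 0.5% in aspect ratio,
which is what the electrodeformation chain needs.

## Problem sizes and determinism

Every generator takes an explicit integer seed, saves and restores the
global RNG state, and is bit-reproducible; pipeline reports embed their
configuration and contain no timestamps, so identical runs are
byte-identical. The validation studies use the conditions of the
measurements they emulate: 3000-frame contour stacks of 256 points at
$R = 15\,\mu$m and reduced tension 5 for rigidity recovery (100
independent vesicles per rigidity); ten vesicles of 3–10 µm radius with
2% aspect-ratio noise per capacitance fit (200 replicates); 256×256
height maps with 2 nm tilt, 40% patch coverage and 0.1 nm roughness (100
maps); 5-second traces at 100 frames/s with 1% noise (200 replicates);
five tension–area points at 1–8% strain with 3% tension noise (200
replicates). Medians over replicates are compared at 10% tolerance in the
acceptance script, closed-form chains at their printed precision.

## Known limitations

* The flicker model assumes quasi-spherical, low-tension vesicles; it is
  not a renormalized-tension theory and will bias $\kappa$ for tense or
  strongly deflated vesicles (which quality control excludes).
* Only the crossing point of a frequency sweep is modelled; the full
  electrokinetic shape response across frequency is out of scope.
* The AFM chain expects user-supplied (or test-supplied) crops; it does
  not segment patches automatically and does not deconvolve the tip.
* Temporal correlation of contour fluctuations, camera shot noise, and
  phase-contrast halo optics are not simulated; conclusions about real
  data should lean on the quality-control filters, not on the recovery
  numbers alone.
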