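---
title: "Partial-volume correction and group mapping for MRSI: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partial-volume correction and group mapping for MRSI: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrsipvc)
```

This vignette explains the models implemented in `mrsipvc`, the choices
behind their defaults, and what the package's validation on synthetic
data does and does not demonstrate about real acquisitions.

## The acquisition point-spread function

An MRSI acquisition samples k-space on a coarse matrix (default 44 × 44
over a 220 mm field of view, i.e. 5 mm nominal in-plane voxels). Two
features of the reconstruction shape the spatial response:

* an **elliptical k-space shutter** — only points inside the inscribed
  ellipse of the acquisition matrix are sampled, which shortens the scan
  but widens the response;
* a **Gaussian spatial-response apodization** applied when over-discretized
  data are down-sampled back to the acquisition grid, which suppresses the
  far-reaching sinc ringing that truncated sampling would otherwise
  produce (this ringing is what carries extracranial lipid signal deep
  into the brain).

`build_psf()` forms the kernel as the magnitude of the inverse DFT of
(shutter × Gaussian apodization), zero-padded to the 1 mm anatomical
grid, normalized to unit sum. `measure_fwhm()` reports the in-plane full
width at half maximum using linear interpolation between grid points
(sub-grid precision without fitting a model), averaging the two in-plane
axes through the peak.

**Choice of the response width.** The apodization is parameterized by the
FWHM of its *spatial* Gaussian response. The default is 1.5 × the nominal
in-plane voxel size (7.5 mm for the default geometry). This value was
fixed once, on two grounds: it is in the conventional range for Gaussian
target responses in over-discretized MRSI reconstruction, and under this
package's PSF construction it reproduces the composite 8.75 mm FWHM
characteristic of the reference protocol:

```{r psf}
psf <- build_psf(acq_geometry())
psf$fwhm_mm
```

A narrower response (5 mm, the nominal voxel size) yields a 7.7 mm
composite width under the same construction; the parameter is exposed as
`response_fwhm_mm` so a site can match its own reconstruction. With a
full shutter and no apodization the kernel reduces to the separable
|sinc| response of a boxcar spectrum (FWHM ≈ 1.21 × voxel size), which
the test suite checks against a direct-DFT oracle at every grid point.

The PSF is modelled in-plane only; the through-slice profile is treated
as an ideal 10 mm boxcar, since the shutter and over-discretization act
in-plane. Segmentation convolution (`convolve_fractions()`) therefore
runs per 1 mm sub-slice, with **reflective boundary handling** so that no
tissue volume is artificially lost at slab edges (total tissue volume is
conserved to numerical precision, and unit-sum kernels preserve
constants).

## Partial-volume correction

A voxel's metabolite signal is modelled as a weighted sum of pure-tissue
contributions with CSF contributing nothing (metabolite concentrations in
CSF are negligible):

$$M = f_\mathrm{GM}\, s_\mathrm{GM} + f_\mathrm{WM}\, s_\mathrm{WM}.$$

Dividing by the tissue fraction $f_\mathrm{GM}+f_\mathrm{WM}$ and writing
$g = f_\mathrm{GM}/(f_\mathrm{GM}+f_\mathrm{WM})$ for the normalized GM
fraction gives a line in $g$ whose extrapolations to $g=1$ and $g=0$ are
the pure-GM and pure-WM levels. `fit_pure_tissue()` estimates them by
unweighted ordinary least squares over QA-surviving voxels, using
**PSF-adjusted fractions aggregated to the native grid** so the covariate
sees the same voxel bleeding as the data.

Design choices that were genuinely open:

* **Tissue-normalized regression.** The regression uses
  $y = M/(f_\mathrm{GM}+f_\mathrm{WM})$ against $g$ (the formulation used
  in tissue-fraction spectroscopy analyses), rather than raw $M$ against
  $g$. The normalized form makes the two axes meaningful at partial CSF
  occupancy and keeps the extrapolations interpretable as pure-tissue
  ratios.
* **`min_tissue = 0.5`.** Voxels more than half CSF are excluded from the
  regression: their normalized values divide by a small tissue fraction
  and dominate the fit with unstable leverage. The threshold is a
  configuration parameter.
* **One global (s_GM, s_WM) pair** per metabolite per subject; regional
  regression is out of scope.
* **Negative extrapolations are retained with a warning**, never clipped:
  silent clipping would bias group statistics.

`redistribute_voxel()` then moves signal within (and only within) each
native voxel: every 1 mm cell receives
$M \cdot p(r)/\overline{p}$ with
$p(r) = f_\mathrm{GM}(r)\,s_\mathrm{GM} + f_\mathrm{WM}(r)\,s_\mathrm{WM}$
evaluated on the PSF-adjusted fractions. By construction the mean over
the voxel's cells equals the measured value exactly (asserted to 1e−12 in
the tests): partial-volume correction changes local contrast, never local
averages. Voxels with no GM/WM content are flagged and set missing.

**What "recovering the truth" means.** The phantom's central oracle runs
the noiseless forward model (pure-tissue signal from raw fractions →
PSF blur → native-voxel averaging) and then the full correction with
matched inputs. The regression recovers $s_\mathrm{GM}, s_\mathrm{WM}$
exactly (to < 1e−6), and the corrected map equals the
*acquisition-domain* truth — the pure-tissue model evaluated on the
PSF-adjusted fractions — to 1e−6 wherever GM+WM occupy at least half the
cell. The pre-blur truth is not pointwise recoverable at GM/WM borders by
any method that, like this one (and the underlying published procedure),
redistributes within voxels using blurred fractions; away from borders
the two truths coincide. The phantom therefore stores both
(`truth` and `truth_adj`).

A related empirical note: over a deep-GM nucleus region of interest the
corrected map's mean moves toward the pure-GM level (the point of PVC,
asserted in the tests), but its *standard deviation* in the phantom is
slightly lower than that of the uncorrected nearest-regridded map,
because redistribution produces a smooth PSF-consistent field while the
uncorrected map carries block-quantization spread from voxels straddling
the ROI border. Reports of increased ROI spread after PVC on in-vivo
cohort data reflect noise amplification at border zones and intersubject
anatomy, which the desk-scale phantom does not emulate; the package
asserts the mean shift only.

## Steady-state T1 correction

At short TR the longitudinal magnetization does not fully recover; a
metabolite with T1 longer than the tCr reference is relatively
suppressed. For a spoiled acquisition at flip angle $\alpha$ and
repetition time TR,

$$E(T_1) = \frac{\sin\alpha\,(1 - e^{-TR/T_1})}{1 - \cos\alpha\, e^{-TR/T_1}},$$

and `t1_correction_factor()` multiplies the ratio map by
$E(T_{1,\mathrm{tCr}})/E(T_{1,\mathrm{met}})$ with tissue-specific T1s.
Defaults: $\alpha = 35°$, TR = 300 ms. At the 1 mm level the GM and WM
factors are mixed by the local tissue fractions,
$(f_\mathrm{GM} F_\mathrm{GM} + f_\mathrm{WM} F_\mathrm{WM})/(f_\mathrm{GM}+f_\mathrm{WM})$
— the simplest rule consistent with applying tissue-specific values to a
tissue-mixed cell. The T1 table ships as an editable data frame of
representative 7 T values (`t1_table()`, labelled as such); studies
should substitute values for their field strength and literature of
choice. No per-molecular-subgroup or regional T1 variation is modelled,
and no absolute (water-referenced) quantification is attempted.

## Quality-assurance filtering

The four keep-criteria are strict inequalities — SNR > 3,
FWHM < 0.15 ppm, Lip13ab/tCr < 2, CRLB < 50 %SD — so a voxel exactly at a
threshold is discarded; this is the literal reading of the filter
definitions. CRLB filtering is per metabolite, and because all maps are
ratios over tCr, a voxel whose tCr CRLB exceeds the threshold is removed
from *every* metabolite map (`propagate_tcr_filter()`, idempotent). Each
mask records which criteria removed each voxel. The linewidth criterion
uses the fitting-stage FWHM output (not a separate water-reference
linewidth), and the lipid criterion uses the fitted Lip13ab amplitude
ratio as provided — no spectral fitting is re-done here. Relative (%SD)
CRLB filtering is the default; note that CRLB-based filtering can bias
group comparisons where metabolite levels change with disease, which is
why the thresholds are configuration, not constants.

## Regridding, normalization, averaging

`regrid_nearest()` subdivides each native voxel into its 250 anatomical
cells (nearest-neighbor by cell center, half-open voxel extents) — a pure
relabelling that conserves per-voxel values exactly and lets the
subsequent transforms operate at 1 mm. `apply_transform_chain()` composes
the rigid slice-to-anatomy matrix, the affine anatomy-to-reference
matrix and an optional dense displacement field into a **single**
resampling step (one interpolation, not three — each extra interpolation
low-pass filters the map, which the tests demonstrate against an analytic
field oracle). Trilinear interpolation is the default for continuous
metabolite maps and is missing-aware (weights renormalized over present
neighbors); nearest is used for masks and QA maps. The displacement field
follows the common resampling convention: defined on the reference grid,
in mm, added to the reference coordinate before the inverse affines.

`average_with_density()` counts, per reference cell, how many subjects
contribute a value after QA filtering and normalization (the data
density), reports mean and SD (n−1 denominator; SD missing below two
subjects), and masks cells with density below 3 — the default mirrors the
rule that averaged-map voxels supported by fewer than three datasets are
removed. `roi_statistics()` reports regional means ± SD over the
density-passing cells and flags empty regions as absent rather than zero.
Reference space is configurable; nothing in the package downloads or
assumes a specific atlas.

## The digital phantom

`phantom_spec()` describes a synthetic study the pipeline can be run on
end to end: a 220 × 220 × 20 mm slab at 1 mm containing an elliptical WM
background, a cortical GM ribbon, two ventricular CSF bodies and two
deep-GM nuclei adjacent to them; pure-tissue ratios per metabolite
(defaults: Glu 1.1/0.7, tCho 0.18/0.25, tNAA 1.3/1.5 for GM/WM — healthy
human ranges with the conventional contrast directions); additive
Gaussian noise on native-grid values (default SD 0.05, a realistic
post-fit ratio uncertainty); and QA defect zones emulating the artifact
patterns of crusher-coil acquisitions: an overcrushed cortical rim with
sub-threshold SNR and an anterior zone with broadened linewidth. CRLB is
tied to SNR by a configurable inverse map, reflecting their empirical
relationship.

Structure edges are antialiased: in-plane positions are supersampled 8×
per axis and the through-slice extent of each ellipsoid/box is integrated
analytically, keeping boundary-cell coverage within 0.02 of a dense
oracle. Noise is added to native-grid *values*, not spectra: the pipeline
under test starts at fitted maps, so time-domain simulation would add
machinery without exercising any additional code path. Identical spec and
seed regenerate a study bit-identically.

What the phantom does **not** emulate: B0/B1 field structure, lipid
spatial patterns beyond the rim defect, spectral overlap and fitting
error correlations, intersubject anatomical variability, or registration
error (transforms are inputs). Passing the round-trip and recovery tests
therefore demonstrates the correctness of the correction algebra and its
implementation, not the end-to-end accuracy of any particular in-vivo
protocol.

## The macromolecular baseline

`synthesize_mm_profile()` renders the macromolecular signal as nine
Gaussians at the standard chemical shifts (0.94, 1.29, 1.42, 1.79, 2.04,
2.31, 2.75, 3.02, 3.25 ppm), with components grouped (MM12+MM14,
MM17+MM20, MM30+MM32) so each group scales through a single factor,
mirroring the amplitude-ratio constraints used when fitting overlapping
MM resonances. Centers are the established values; linewidths (default
0.10 ppm FWHM) and relative amplitudes are declared defaults, as measured
fit parameters for this lineshape model are site-specific. The profile is
used generatively (phantom enrichment, basis export), not for fitting.

## Numerical choices and problem sizes

* FFT-based convolution with symmetric (edge-inclusive) reflective
  padding; kernels cropped to their significant support (relative
  threshold 1e−12) and renormalized.
* FWHM measurement interpolates linearly; kernels must have a unique
  peak, flat kernels raise an error, single-cell peaks report ≤ 2 grid
  steps.
* Ellipse/shutter center at index N/2 for even N (DFT convention);
  half-open cell extents with lower-index ties in nearest lookup.
* Regression statistics (SEs, R²) are computed directly from the
  residuals so perfect fits are handled without special-casing.
* The test suite exercises the full 220 mm protocol once (acceptance
  round-trip) and otherwise uses a 110 mm, 22 × 22, single-slice
  configuration and fixture sizes of 200–500 voxels with 10–100 seeded
  replicates — sizes at which every oracle (brute-force enumeration,
  direct DFT, closed forms, independent OLS) can be evaluated exactly.

## Known limitations

* Through-slice bleeding is not modelled (ideal 10 mm boxcar).
* One global pure-tissue pair per metabolite and subject; the linear
  tissue-fraction model assumes stable pure-tissue ratios, so corrections
  in structurally abnormal tissue (tumor, lesions) are unreliable.
* T1 correction is per metabolite and tissue only, with literature
  defaults; B1 inhomogeneity and subgroup-specific relaxation are not
  corrected.
* No registration estimation, brain extraction or segmentation: tissue
  fractions and transforms are inputs.
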