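---
title: "Quantifying cervical spinal cord motion from phase-contrast MRI"
author: "cordmotion authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cervical spinal cord motion from phase-contrast MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cordmotion)
```

## The measurement problem

The cervical spinal cord is not static: with every heartbeat it performs a
small pulse-synchronous cranio-caudal oscillation, on the order of a few
tenths of a cm/s in velocity and roughly half a millimetre of total
excursion. In degenerative cervical myelopathy, motion at and around a
stenotic segment is increased, so cord motion is a candidate imaging
biomarker — provided it can be measured in a standardized, reliable way.

Cardiac-gated axial phase-contrast MRI (PC-MRI) encodes through-plane
velocity into the signed grey value of each voxel. With a velocity
encoding limit (venc) of 2 cm/s and a 20-phase cine acquisition per
cervical segment (C2–C7), one cardiac cycle of cord motion is captured per
segment. `cordmotion` implements the evaluation chain from the phase
images to cohort-level statistics.

## The evaluation model

For one segment, let $g_{i}$ be the mean grey value over the cord ROI at
cardiac phase $i = 1, \dots, T$ (here $T = 20$), with grey full scale
$G = 4096$. The chain is:

1. **ROI averaging** — an ellipsoid ROI of 30.52&nbsp;mm² is placed
   mid-centred in the cord; a pixel belongs to the ROI iff its centre
   satisfies the ellipse inequality in mm coordinates
   (`roi_mean_greyvalues()`).
2. **Velocity conversion** — $v_i = g_i / G \cdot \mathrm{venc}$
   (`grey_to_velocity()`); positive values are cranial.
3. **Phase-drift correction** — PC-MRI velocities carry a
   scanner-dependent baseline offset ("phase drift", typically +0.2 to
   +0.3&nbsp;cm/s on the scanners this protocol targets). Because the
   cord starts and ends the cycle at the same position, its net motion
   must be zero, so the drift estimate is the waveform mean:
   $\hat d = \bar v$, and $v_i' = v_i - \bar v$
   (`correct_phase_drift()`). Correction is an explicit, idempotence-
   guarded step: raw readouts remain obtainable for drift-sensitivity
   analyses, and correcting twice is an error rather than a silent no-op.
4. **Readouts** (`compute_readouts()`) — maximum cranial velocity
   $\max_i v_i'$, maximum caudal velocity $\min_i v_i'$, amplitude
   (their difference, drift-free by construction), and displacement
   $\sum_i |v_i'| \cdot RR/T$ in cm — the rectified area under the
   velocity curve by the left rectangle rule, deliberately *not* refined
   to a trapezoid, to match the protocol's stated arithmetic. The RR
   interval is stored in ms (integer, the scanner convention) and
   converted to seconds here, which is what makes displacement land in
   the observed 0.03–0.06 cm range.

```{r example}
v <- evaluate_template(motion_template(), max_cranial = 0.186,
                       max_caudal = -0.259)
w <- velocity_waveform(v + 0.25, rr_interval_s = 0.95)  # drift-contaminated
cw <- correct_phase_drift(w)
cw$drift_estimate
unlist(compute_readouts(cw))
```

## The synthetic cohort: what it emulates

No public PC-MRI cord-motion dataset exists, so the package carries a
first-class generator (`synthesize_cohort()`) that produces the inputs
the analysis assumes, with known ground truth:

* **Waveform shape** — nearly no motion in the first half of the cycle,
  then a caudal lobe followed by a cranial lobe. Lobes are
  compact-support raised-cosine bumps $\cos^{2p}$ in cycle-fraction
  time, peaks at cycle fractions 0.65 and 0.85 (read qualitatively from
  the published group curves — they are configuration, not ground
  truth), half-width 0.12 capped so no lobe spills into the quiescent
  half. Compact support was chosen over Gaussian bumps deliberately:
  it makes first-half quiescence exact rather than
  approximate-in-the-tails, so the shape property (first-half
  $|v| < 5\%$ of amplitude) holds for *every* generated waveform, not
  just typical ones.
* **Exact peak contract** — peak phases are snapped to the nearest grid
  sample and the two lobe scales solve a 2×2 linear system, so the
  gridded extrema equal the requested peaks exactly and
  parameter-recovery tests can assert equality up to the quantization
  bound venc/4096 ≈ 0.00049 cm/s instead of a fuzzy tolerance.
* **Zero-mean by construction** — the lobe mass is redistributed over
  the post-quiescent samples so the exact waveform has mean zero. This
  makes the injected drift the unique waveform mean, i.e. drift
  recovery is well-posed, mirroring the zero-net-motion assumption the
  correction itself relies on.
* **Displacement matching** — the raised-cosine exponent $p$ is a
  monotone displacement knob at fixed peaks (spikier lobes sweep less
  area). Per subject, $p$ is tuned by root bracketing so the exact
  waveform's rectified AUC equals the subject's displacement draw.
  Targets outside the attainable band for the drawn peaks are clamped
  to its edge; the realized value is what enters the ground-truth
  table. Measured over the C5 draw distribution the clamp bias on the
  cohort mean is below 0.001 cm.
* **Subject draws** — per-segment (mean, SD) pairs for both peaks and
  displacement default to normative healthy-cohort values
  (`segment_reference_values()`). The three standardized deviates share
  a latent motion-magnitude factor (pairwise correlation 0.8):
  physiologically, peaks and displacement scale together, and the
  correlation keeps displacement targets attainable for the drawn
  peaks. Peak asymmetry is capped at 0.35 ≤ cranial/|caudal| ≤ 1/0.35 —
  with zero net motion and a quiescent half-cycle, one lobe's area must
  balance the other's, so extreme asymmetry is physically impossible.
* **Acquisition physics** — velocities (plus drift) are encoded as
  `round(v / venc * 4096)`, in-ROI pixels carry the motion signal,
  every other pixel carries the drift-only (static tissue) signal, and
  integer-rounded Gaussian noise (default SD 50 grey units ≈
  0.024 cm/s per pixel) is added per pixel *before* ROI averaging, so
  the variance reduction of averaging ~120 pixels is reproduced.
  Encoding beyond full scale raises an error; clipping is out of scope
  (a healthy cohort at venc 2 cm/s does not saturate).
* **Drift** — normal with mean 0.25 and SD 0.025 cm/s, fresh per scan,
  keeping draws within the 0.2–0.3 cm/s band reported for this scanner
  class.
* **RR intervals** — normal, 1000 ± 100 ms, rounded to integer ms
  (age-60 resting heart rates).
* **Test–retest** — retest truths are the baseline truths perturbed by
  a within-subject SD of 0.4 × the between-subject SD, with fresh drift
  and RR per scan. That ratio targets corrected test–retest ICCs in the
  high-0.8/0.9 range while the fresh drift degrades *raw* displacement
  reliability — the qualitative phenomenon the reliability machinery
  must be able to demonstrate.

What the generator does **not** emulate: spatial drift gradients and
eddy-current structure, partial-volume CSF contamination at the cord
boundary, respiratory modulation, coil-sensitivity profiles, or
inter-rater ROI placement behaviour beyond a simple centre jitter. A
green parameter-recovery test therefore establishes the correctness of
the evaluation arithmetic, not the clinical accuracy of the protocol.

## The statistics layer

`cohort_table()` joins the long readout table with subject covariates and
enforces the unique (subject, scan, rater, segment) key;
`apply_exclusions()` removes flagged subjects (e.g. incidental stenosis)
with an audit message. `derive_biometrics()` computes before/after blood
pressure means and MAP = diastolic + (systolic − diastolic)/3.

* **Segmental comparisons** — `friedman_intersegment()` runs the
  Friedman test over segments with subjects as blocks, then Dunn tests
  on the within-subject mean ranks with Bonferroni adjustment over the
  15 segment pairs. The source protocol reports pairwise p-values
  without naming its post-hoc method; Dunn–Bonferroni is the default
  pairwise follow-up of the statistics package used there, which is why
  it was chosen — a documented deviation risk. The fully-tied
  degenerate case (all subjects constant across segments) is defined as
  statistic 0, p 1.
* **Reliability** — `icc_two_way()` implements ICC(A,k) of McGraw &
  Wong: two-way model, absolute agreement, average measures,
  $(MS_R - MS_E)/(MS_R + (MS_C - MS_E)/n)$, with the significance F
  test $MS_R/MS_E$ on $(n-1, (n-1)(k-1))$ df, matching SPSS output
  conventions. Zero between-subject variance yields a defined
  non-positive ICC with a warning, not an exception. The test suite
  checks the implementation against an independent `lm()`-based
  sums-of-squares oracle to 1e−10.
* **Correlations** — `spearman_correlations()` with mid-rank ties,
  per segment or pooled across all segments. The pooled scope stacks
  segment-level observations (n ≈ subjects × segments) and treats them
  as independent, mirroring the protocol's reported n; this ignores
  within-subject correlation and is documented as such — per-segment
  coefficients are the conservative alternative.
* **Missing data** — pairwise deletion per analysis (a subject with a
  missing covariate drops from that correlation only), matching the
  varying n of the source tables.
* **SD convention** — sample SD (n−1) throughout.

## Numerical and interface choices

* Grey values are signed integers in ±4096; the velocity map is exact
  rational arithmetic up to double precision, and the quantization step
  venc/4096 is the resolution floor every recovery bound is stated in.
* Pixel-inclusion for the ROI is the pixel-centre test, 0-based
  row/col coordinates, pixel centres at integer coordinates; this exact
  rule is part of the fixture-format contract since the DICOM viewer
  used clinically does not document its own rule.
* Two on-disk formats round-trip bit-identically: a plain-text fixture
  container (deterministic, diffable, no DICOM machinery needed) and a
  minimal DICOM subset (Explicit VR little endian, one file per cardiac
  phase, TriggerTime ordering with InstanceNumber tie-break,
  NominalInterval as RR, rescale slope/intercept applied at read). The
  DICOM layer is self-contained because no DICOM library is available
  in the supported environment; it is not a general parser.
* Saturated grey values (|g| = full scale) set a `saturated` flag on
  the waveform rather than erroring: venc aliasing is plausible in
  pathology and should be a QC decision downstream.
* Static-tissue-based and phantom-based drift correction are
  deliberately out of scope; the zero-net-motion correction is the
  protocol's contribution precisely because static-tissue references
  proved unreliable between raters.

## Known limitations

* Amplitudes reported on published group means can differ from
  max-cranial-minus-max-caudal of those *rounded* means by ~0.001–0.002;
  the identity holds per subject, and the package computes it per
  subject.
* The ROI aspect ratio (1.6 right-left : anterior-posterior at
  30.52 mm²) is a package default; only the area is published.
* Published reliability tables and correlation coefficients depend on
  the original clinical scans and are not reproducible from synthetic
  data; the package reproduces the machinery and verifies it against
  oracles and direction-only checks (e.g. corrected test–retest ICC for
  displacement must exceed the raw one on a drift-perturbed cohort).
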