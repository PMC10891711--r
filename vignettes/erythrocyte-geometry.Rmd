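---
title: "Erythrocyte geometry from diameter and MCV: models, protocol, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Erythrocyte geometry from diameter and MCV}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbcgeom)
```

## The problem

The mammalian erythrocyte is a biconcave disc. Its volume is trivial to
obtain — the MCV is part of every complete blood count — and its mean
diameter is read off a stained smear. Thickness and membrane surface area,
by contrast, require micropipette aspiration: precise, but slow, skilled
work on instrumentation most zoologists and veterinarians do not have. Yet
the surface area, and especially the surface-area-to-volume ratio, governs
the cell's deformability — its ability to squeeze through capillaries
narrower than its own diameter — and shrinks in spherocytosis, sickle cell
disease, malaria and other conditions.

The exact biconcave profile is a Cassini-oval surface of revolution whose
area involves elliptic integrals. This package deliberately avoids that
machinery and works with simple solids whose formulas close under the two
measurable inputs.

## The models

All lengths are µm; 1 µm³ = 1 fL. For a cell of diameter $d$ and thickness
$t$ (rim-to-rim, at the torus):

* **Sphere** — $V_s = \frac{\pi}{6}d^3$, $SA_s = \pi d^2$. Thickness-free;
  only correct for genuinely spherical cells.
* **Cylinder** — $V_c = \frac{\pi}{4}d^2 t$, $SA_c = \pi d(\frac{d}{2}+t)$
  (two faces plus the lateral wall). Its virtue is invertibility:
  $t = 4\,\mathrm{MCV}/(\pi d^2)$.
* **Biconcave spheroid** — a large oblate spheroid of rotation about the
  minor axis, minus two small cap spheroids each standing for twice the
  volume of one concavity:
  $$V_b = \tfrac{4}{3}\pi A^2 B - 2\cdot\tfrac{4}{3}\pi a^2 b, \qquad
    SA_b = 2\pi A^2 + 2\pi A B\,\frac{\sinh^{-1} e}{e},$$
  with $e = \sqrt{A^2-B^2}/B$ the second eccentricity. The standard
  approximations $A = d/2$, $B = \tfrac{2}{3}t$, $a = d/4$, $b = t/8$
  reduce these to
  $$V_b = \tfrac{29}{144}\pi d^2 t, \qquad
    SA_b = \pi d\left(\tfrac{d}{2} + \tfrac{2}{3}t\,\tfrac{\sinh^{-1}e}{e}\right).$$
  Note $V_b/V_c = 29/36$ identically — the two volume models are
  interchangeable up to a constant 19.4% offset in the cap correction, and
  in practice both track the MCV closely.
* **Elliptical cylinder** — camelid erythrocytes are flattened ellipses
  without concavity; with full major/minor diameters $a \ge b$:
  $V = \frac{\pi}{4}abt$, $SA = \frac{\pi}{2}(a+b)t + \frac{\pi}{2}ab$
  (wall with perimeter $\approx \pi(a+b)/2$ plus two elliptical faces).
  Both reduce exactly to the circular cylinder at $a = b$.

The $SA_b$ expression is not an approximation of the spheroid: it is the
exact closed form for the oblate spheroid's surface, which the test suite
verifies against an independent surface-of-revolution quadrature
($2\pi\int \sqrt{x^2 + (xx')^2}\,dz$ over the ellipse, a smooth integrand)
to relative error below $10^{-9}$. The approximation lies in using the full
spheroid's surface for the biconcave cell — the concavities add membrane
that the caps' *volume* correction does not capture — and in the $B, a, b$
substitutions themselves.

### The eccentricity domain

$e$ is real only while $A \ge B$, i.e. $t/d \le 3/4$. At the boundary the
spheroid degenerates to a sphere: $\sinh^{-1}(e)/e \to 1$ and
$SA_b \to \pi d^2$ continuously, so the package treats $t/d = 3/4$ as
computable. Beyond it the eccentricity is imaginary and the surface has no
real value; this is surfaced as a first-class *not computable* state — a
flagged `NA` with a warning from `biconcave_surface()`, a `biconcave_computable`
field in protocol results, rendered `"n.c."` in reports — never a silent
`NaN`. Near $e = 0$ the quotient $\sinh^{-1}(e)/e$ is evaluated by its
series $1 - e^2/6 + 3e^4/40$ for $e < 10^{-4}$, where the direct quotient
loses digits to cancellation; the tests check the seam is smooth to 12
significant digits against quadrature.

## The estimation protocol

`surface_area_protocol(diameter, mcv)` chains four steps: MCV (optionally
from `mcv_from_count()`), measured diameter, thickness by cylinder
inversion, then surface area by the model the validity screen selects.

The screen implements two smear-level rules of thumb plus the hard domain:

1. **central pallor** absent → cells are probably spherical → reject;
2. **thickness:diameter ratio** ≥ 0.5 → reject;
3. $t/d > 3/4$ → biconcave surface not computable at all.

Rejected cells fall back to the sphere surface computed from the *measured*
diameter. For hereditary-spherocytosis-range inputs (e.g. d = 5.9 µm,
MCV = 80 fL) the raw ratio is 0.496: the screen rounds the ratio to one
decimal place (half away from zero) *before* comparing, so this case fails
as 0.5 — matching how such borderline verdicts are reported in practice.
`ratio_rule = "unrounded"` switches to the raw comparison; the choice is
recorded in the result. `sphere_diameter = "mcv_equivalent"` replaces the
measured diameter with $(6\,\mathrm{MCV}/\pi)^{1/3}$ for cross-checking.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `hct_unit` | `"fraction"` | hematocrit unit; never guessed from magnitude |
| `central_pallor` | `TRUE` | smear observation; the assumed default is noted in results |
| `ratio_rule` | `"rounded_1dp"` | ratio compared after 1-dp rounding (see above) |
| `sphere_diameter` | `"measured"` | diameter used by the spherical fallback |
| `d_range`, `ratio_range` | 2–10 µm, 0.15–0.9 | synthetic generator ranges |

## Model evaluation and the packaged tables

`evaluate_models()` builds the cross-species comparison: per-record model
predictions, absolute percentage errors against a measured reference (MCV
for volumes, micropipette surface areas for surfaces), and the per-model
MAPE. Records without a reference are dropped pairwise, never imputed.

Two routes exist for the calculated columns. `columns = "recompute"`
evaluates the closed forms on each record's $(d, t)$. `columns = "printed"`
takes calculated columns already present in the table as given. The second
route exists because the packaged comparative tables — like most published
tables — display inputs rounded to 1–2 significant decimals while their
calculated cells were produced from unrounded source data. Three
discrepancies in the packaged tables are worth knowing:

* the published biconcave *volume* column nearly equals the cylinder column
  rather than $\tfrac{29}{36}$ of it, so it cannot come from the
  cap-subtracted formula as stated; the package computes
  $V_b = \tfrac{29}{144}\pi d^2 t$ and does not force agreement;
* the published biconcave *surface* cells (e.g. 136.5 µm² for the human
  discocyte) are not reproducible from the $SA_b$ formula with the
  displayed $d, t$ (which give ≈104.5 µm²); the MAPE comparisons therefore
  run on the printed columns, where the footers do reproduce;
* the published cylinder-surface MAPE footer (3.2%) disagrees with its own
  printed columns, which yield 3.8%; the package reports what the columns
  give.

## The synthetic generator

`generate_rbc_sample()` draws diameters uniformly over 2–10 µm — the span
of real mammalian erythrocytes, from *Tragulus javanicus* (~2 µm) to the
largest monotreme cells (~9–10 µm) — and thickness ratios uniformly over
0.15–0.9, deliberately covering the valid (< 0.5), invalid (≥ 0.5) and
not-computable (> 0.75) regimes so property sweeps exercise every branch.
The MCV column is the cylinder volume of each pair, making protocol
round-trips exact by construction. What the generator does *not* emulate:
measurement error in smear diameters, correlated $d$–$t$ allometry across
species, non-uniform trait distributions, or abnormal morphologies beyond
what the ratio encodes. Passing property tests therefore certify the
mathematics and the decision logic, not field performance on noisy
measurements.

Test problem sizes — a $10^4$-point sweep for the algebraic invariants and
a few dozen quadrature comparisons — keep the full suite in the
single-digit seconds while covering the (d, t) plane densely.

## Known limitations

* The biconcave surface uses the full oblate spheroid's area; the extra
  membrane lining the concavities is not modelled beyond the cap volume
  correction, so $SA_b$ is a lower-biased estimate for deeply concave cells.
* Whether $B$ should be two-thirds of the full thickness or of the
  half-thickness is ambiguous in the morphometric literature; the package
  adopts the full thickness, which keeps $V_c$ and $V_b$ within 20% and
  reproduces the worked protocol cases.
* The validity screen is a pair of rules of thumb, not a classifier; cells
  near the 0.5 ratio boundary genuinely straddle morphologies, which is why
  the rounding rule is exposed as an option.
* No statistical inference is provided (no correlation or significance
  testing of model fits); the MAPE is a descriptive error summary.
* Diameters must be measured on round cells with central pallor, oriented
  flat on the slide; the package cannot detect smear artefacts.
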