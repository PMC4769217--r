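---
title: "Methods: paint-based TBSA estimation, Parkland planning and the consultation workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paint-based TBSA estimation, Parkland planning and the consultation workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burnflow)
```

## The estimation model

Burn extent is estimated from a *painting*: per body view (anterior,
posterior) and per depth category, a binary raster mask of the pixels the
assessor marked as burned. The avatar partitions each view's silhouette
into named body regions; a region `r` painted with fraction
`f_r = |paint ∩ region| / |region|` contributes `f_r * LB(r, age)` percent
of total body surface area, where `LB` is the Lund–Browder chart
percentage of that region in the patient's age band. Summing over regions
and depths gives per-depth TBSA; the fluid-eligible total is the sum over
partial-thickness, full-thickness and indeterminate paint, while
superficial paint is reported separately and never enters fluid
calculations.

The model's assumptions are worth stating plainly:

- **Pixel area is the unit of evidence.** Within one region, every pixel
  carries the same share `LB(r, age)/|region|` of body surface. The avatar
  is a 2-D schematic, so this is an allocation device, not a projection of
  true anatomy; its accuracy is bounded by how well the assessor paints
  and how reasonable the region partition is.
- **The partition is strict.** Region masks are pairwise disjoint and
  their union equals the silhouette exactly, which gives the conservation
  property `Σ_r f_r |region_r| = |paint|` and makes a full-silhouette
  painting yield exactly 100% in every age band (each table row is
  normalised to 100). Both facts are enforced by validators and tests
  rather than assumed.
- **Painting outside the body is user error.** Raw masks are clipped to
  the silhouette (set intersection, idempotent) before any counting, so
  stray strokes cannot inflate TBSA.
- **One depth per pixel.** Where the same pixel carries several depths,
  the deepest wins (full > partial > indeterminate > superficial). The
  choice is conservative for resuscitation and makes resolution
  deterministic; the union of painted pixels is preserved exactly.
- **Indeterminate counts as burn.** Only superficial burns are excluded
  from fluid calculations; an area that cannot yet be classified is
  treated as burn area until reassessed, which is the conservative
  clinical reading.

## The packaged avatar and chart

The avatar artwork of the original phone application is not published, so
the package ships a synthetic stand-in with the same structural contract:
two 480×800-pixel views (a typical handset screen; `scale` shrinks it
proportionally), 33 rectangular regions with per-side laterality, and a
body-part category on each region matching the photo-tagging index.
Rectangles keep pixel counts exact and the partition trivially auditable;
real artwork can replace it at run time via `load_avatar()` (PNG masks +
YAML manifest) without touching any computation.

The Lund–Browder chart itself is shipped as an editable YAML asset with
the standard published values: per-side head 19/17/13/11/9/7, thigh
5.5/6.5/8/8.5/9/9.5 and lower leg 5/5/5.5/6/6.5/7 percent across age
bands [0,1), [1,5), [5,10), [10,15), [15,18), [18,∞) years, with the
age-constant areas (neck, trunk, buttocks, genitalia, arms, hands, feet)
as usually tabulated. Whole-body areas are split evenly between the
anterior and posterior region of each area. Every row must sum to 100
within 1e-6 — the loader rejects anything else — so edits to the asset
cannot silently break normalisation. Band lookup is a step function on
half-open intervals (no interpolation): age 1 uses the [1,5) row, age 18
the adult row. Infants are recorded in months and use `months/12` for
band selection.

## Fluid planning

The Parkland volume is `4 ml × mass [kg] × fluid-eligible TBSA [%]`,
rounded to the nearest millilitre. The 24-hour schedule is anchored at the
time of injury (not presentation): half the volume over hours 0–8, half
over hours 8–24. Numerical conventions: volumes are whole millilitres and
an odd total puts the extra millilitre in the first (more urgent) phase,
so the split conserves volume exactly for every integer total; rates are
reported to 0.1 ml/h. Fluids given before assessment, maintenance fluids
and urine-output titration are out of scope.

Immediate advice is a packaged YAML rule table evaluated entirely
offline: each rule is a predicate over age, stratum, TBSA, cause and
pre-existing conditions, and the baseline entries (cervical spine
management, oxygen, limb elevation, cooling) fire unconditionally. If the
weight is missing the fluid plan is withheld and an explicit "weight
required" advisory is emitted instead — the bundle never fails or blocks
on network state.

## Case records and the consultation workflow

Case records are pseudonymized by construction: the record type has a
reference number (random 12-character URL-safe token, collision-checked
locally) and *no fields* for name, date of birth or address. Entry is
linear (reference → demographics → injury → photos → painting) with
completeness checked in that order; status moves through the state
machine draft → submitted → pending_expert → advised → closed, with
advised → pending_expert reopening a consultation for a follow-up
question, and no other transitions. Every operation appends to an
append-only audit log with UTC ISO-8601 timestamps.

Design choices where the rules left room:

- **Stratum boundary at exactly 18.** The consent strata are "adults",
  "children less than 18 but greater than 6", and "6 years and younger";
  age 18 is therefore adult, age 6 the youngest stratum, with months
  floored into years for infants.
- **Retention as a local sweep.** "Remote wipe after 24 hours" is
  modelled as `purge_unsynced()`: a sweep over the local store driven by
  an injected clock that deletes unsynced cases aged ≥ 24 h and never
  touches uploaded ones. A case is wiped at exactly 24 h (closed
  threshold), and the sweep is idempotent at a fixed clock time.
- **Sessions expire at idle ≥ 5 minutes** (closed threshold: 4 min 59 s
  is active, 5 min 0 s is expired), matching the auto-logout default;
  touching a session resets the timer.
- **Access control** allows exactly the owning HCP, the assigned expert
  and administrators; transfers move rights atomically and the previous
  holder is denied afterwards.
- **The relay is in-process.** The cloud server, SMS/email gateways and
  transport security of a deployment are represented by a pluggable
  gateway interface with an in-memory outbox and a single configured
  on-call expert; rota scheduling, registration approval and the web UI
  are out of scope. Submission against an unreachable relay leaves the
  case in draft with `uploaded = FALSE` for retry — which is precisely
  the state the retention sweep guards.

All time-dependent behaviour (audit stamps, schedules, sessions,
retention, metrics) reads an injectable clock (`fixed_clock()`,
`sys_clock()`); core logic never reads the wall clock directly, which is
what makes the timeout and retention rules testable to the second.

## The fixture generator

`generate_fixture()` produces complete synthetic cases: stratified ages
(defaults: 50% adults, 20% children 7–17, 30% children ≤ 6, reflecting
the large paediatric share typical of emergency burn presentations),
weights plausible for age, coded causes and conditions, placeholder
photographs, and paintings built as unions of randomly chosen whole and
half regions. Because each painted piece is a known fraction of a region,
the fluid-eligible TBSA is available in closed form from pixel counts and
is written next to the case as `ground_truth.json` — an independent
yardstick the pipeline must reproduce exactly. Default targets draw
fluid-eligible TBSA from 5–40% with a 60/25/15 partial/full/indeterminate
depth mix and 1–4 photographs per case. All randomness flows through one
seeded generator; identical specs give byte-identical output trees.

What the generator does *not* emulate: real paint strokes (it paints
region-aligned shapes, not free-hand blobs), photographic content (photos
are opaque placeholder bytes), mis-estimation by the assessor, or any
clinical correlation between cause, depth and extent. Passing tests
therefore demonstrate that the pipeline computes its defined quantities
exactly, not that the avatar-and-painting procedure is clinically
accurate on real patients — the latter needs a validation study, not a
unit test.

## Verification strategy and problem sizes

The oracle tests check the vectorised pixel arithmetic against naive
per-pixel loops that share no code with the implementation: a double-loop
painted-fraction counter, and a TBSA oracle that walks every painted
pixel and adds its region's per-pixel share. The randomized suites use
1000 toy avatars of 10×10 to 100×100 pixels for oracle equivalence,
10,000 random operations for state-machine fuzzing, 100 randomized
ownership configurations for access soundness, and sweeps of all integer
totals up to 10^6 for fluid-split conservation; the packaged avatar is
exercised at scale 0.2 (96×160 per view) so the whole suite stays fast
while pixel counts remain exact at any scale.

## Known limitations

- The avatar is a geometric stand-in; region boundaries are not
  anatomically drawn, and laterality conventions (viewer vs patient
  left) follow the manifest, not rendered artwork.
- The Lund–Browder asset uses the common published tabulation; centres
  that use variant charts should replace the YAML and rely on the
  row-sum validator.
- Coded value sets for causes, conditions and body parts are editable
  stand-ins seeded from the system description's examples, not a full
  published data dictionary.
- The relay simulates contracts (queue, notification, access, sessions),
  not infrastructure: no real SMS gateway, TLS, persistence guarantees or
  concurrent-writer semantics.
- TBSA display rounds to 0.1%; internal arithmetic is double precision
  throughout, and rounding happens only at presentation and at the
  millilitre/rate conventions described above.
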