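# burnflow

Decision-support core for emergency burn care at the point of care,
aimed at health care professionals (HCPs) in settings without immediate
access to a burns specialist, and at developers of mHealth triage tools.
The package is a headless library plus CLI that covers the clinical
computations and the record-handling rules of a store-and-forward burn
teleconsultation system:

- **TBSA estimation.** The burn is "painted" as binary raster masks (one
  per depth category per body view) over a two-view body avatar that is
  strictly partitioned into named regions. For region *r* with painted
  fraction *f_r* (painted pixels / region pixels, after clipping to the
  silhouette) the estimate is the age-adjusted Lund–Browder allocation

  *TBSA% = Σ_r f_r · LB(r, age)*,

  where *LB(r, age)* is the region's percentage of body surface in the
  patient's age band. Superficial burns are recorded but excluded from the
  fluid-eligible total; partial-thickness, full-thickness and indeterminate
  burns count towards it.
- **Fluid planning.** Parkland formula *V [ml] = 4 × mass [kg] × TBSA [%]*,
  with 50% scheduled over the first 8 hours after injury and 50% over the
  following 16 hours, plus an offline rule-based bundle of immediate
  general advice (cervical spine, oxygen, limb elevation, ...).
- **Case workflow.** Pseudonymized coded case records (reference number
  instead of any patient identifier), a linear entry workflow with
  completeness checking, consent/workflow age strata (≤6, 7–17, ≥18
  years), ownership transfer, and a 24-hour retention sweep for unsynced
  data.
- **Consultation relay.** An in-process simulation of the cloud side:
  expert queue with SMS alert, structured five-category expert advice with
  SMS+email notification back, owner/assignee access control, 5-minute
  session auto-logout, and teleconsultation metrics. All time-dependent
  behaviour runs on injectable clocks.
- **Fixtures.** A deterministic generator of synthetic cases whose
  paintings are unions of whole and half regions, so ground-truth TBSA is
  known in closed form and stored next to each case.

## Worked example

A 4-year-old (18 kg) with a partial-thickness burn over the anterior trunk
and a full-thickness burn of the left forearm:

```r
library(burnflow)
avatar <- default_avatar()
lb <- default_lund_browder_table()

painting <- burn_map(list(
  paint_layer("anterior", "partial", avatar$regions$trunk_ant$mask),
  paint_layer("anterior", "full",    avatar$regions$arm_lower_left_ant$mask)))
painting <- resolve_depth_overlaps(painting)

tbsa <- compute_tbsa(painting, age_years = 4, table = lb, avatar = avatar)
tbsa
#> <tbsa_result>
#>   superficial     0.0%
#>   partial        13.0%
#>   full            1.5%
#>   indeterminate   0.0%
#>   fluid-eligible TBSA: 14.5% (superficial 0.0% recorded only)
#>   age band used: [1, 5) years

build_schedule(parkland_volume(18, tbsa$fluid_eligible_percent),
               "2026-03-01T10:00:00Z")
#> <fluid_plan> total 1044 ml over 24 h from injury
#>   0-8 h : 522 ml (65.2 ml/h), 2026-03-01T10:00:00Z to 2026-03-01T18:00:00Z
#>   8-24 h: 522 ml (32.6 ml/h), 2026-03-01T18:00:00Z to 2026-03-02T10:00:00Z
```

The trunk (anterior) carries 13% in every age band and the painted forearm
region 1.5%, so the fluid-eligible TBSA is 14.5%; the Parkland volume is
4 × 18 × 14.5 ≈ 1044 ml, split evenly between the 8 h and 16 h phases
(phase rates differ because the windows do).

The same numbers are available from the shell:

```sh
Rscript inst/cli/burnflow fluids --mass 18 --tbsa 14.5
Rscript inst/cli/burnflow assign-stratum --age 4
```

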