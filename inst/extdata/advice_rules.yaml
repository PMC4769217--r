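# Immediate general-advice rule table, evaluated fully offline.
#
# Each rule has a condition written as an R expression over the fields:
#   age_years (effective age in years), stratum (adult | child_7_17 |
#   child_0_6), weight_known (logical), tbsa (fluid-eligible % TBSA),
#   superficial_tbsa (%), cause (token or NA), conditions (character vector
#   of pre-existing condition tokens).
# Rules fire in order; the advice text of every rule whose condition is TRUE
# is included. The baseline entries reflect standard first-response burn
# care (cervical spine, oxygen, limb elevation); clinical wording can be
# revised here without a code change.
- rule_id: baseline_cervical_spine
  condition: "TRUE"
  advice: "Manage the cervical spine until spinal injury is excluded."
- rule_id: baseline_oxygen
  condition: "TRUE"
  advice: "Give high-flow oxygen and assess the airway for inhalation injury."
- rule_id: baseline_elevate
  condition: "TRUE"
  advice: "Elevate burned limbs to limit swelling."
- rule_id: baseline_cooling
  condition: "TRUE"
  advice: "Cool the burn with running water for 20 minutes; keep the patient warm."
- rule_id: major_burn_referral
  condition: "tbsa >= 20"
  advice: "Major burn: discuss early transfer to a burns centre."
- rule_id: paediatric_major_burn
  condition: "stratum != 'adult' && tbsa >= 10"
  advice: "Significant paediatric burn: seek specialist advice and monitor for hypothermia and hypoglycaemia."
- rule_id: electrical_monitoring
  condition: "!is.na(cause) && cause == 'electrical'"
  advice: "Electrical burn: obtain an ECG and monitor for arrhythmia and deep tissue injury."
- rule_id: chemical_irrigation
  condition: "!is.na(cause) && cause == 'chemical'"
  advice: "Chemical burn: irrigate copiously with water; do not attempt neutralisation."
- rule_id: pregnancy_review
  condition: "'pregnancy' %in% conditions"
  advice: "Pregnant patient: involve obstetric care early."
- rule_id: infant_caution
  condition: "stratum == 'child_0_6'"
  advice: "Young child: reassess fluid needs frequently; small errors in estimation matter more."
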