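# Controlled vocabularies for coded case fields.
#
# The app's full data dictionary is published separately and its coded value
# sets are not reproduced here; these lists are editable stand-ins seeded
# from the examples given in the system description (chronic diseases,
# pregnancy; burn causes as a controlled list). Replace freely -- validation
# only requires tokens to come from these lists.
burn_causes:
  - flame
  - scald
  - contact
  - electrical
  - chemical
  - friction
  - sunburn
  - other
preexisting_conditions:
  - diabetes
  - epilepsy
  - cardiac_disease
  - respiratory_disease
  - hiv
  - malnutrition
  - pregnancy
  - other_chronic_disease
body_part_categories:
  - head
  - neck
  - trunk_front
  - trunk_back
  - buttock
  - genitalia
  - upper_arm
  - lower_arm
  - hand
  - thigh
  - lower_leg
  - foot
sexes:
  - female
  - male
  - other
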