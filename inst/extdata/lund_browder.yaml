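age_bands:
- lower: 0.0
  upper: 1.0
- lower: 1.0
  upper: 5.0
- lower: 5.0
  upper: 10.0
- lower: 10.0
  upper: 15.0
- lower: 15.0
  upper: 18.0
- lower: 18.0
  upper: .inf
percent:
- head_ant: 9.5
  head_post: 9.5
  neck_ant: 1.0
  neck_post: 1.0
  trunk_ant: 13.0
  trunk_post: 13.0
  buttock_left: 2.5
  buttock_right: 2.5
  genitalia: 1.0
  arm_upper_left_ant: 2.0
  arm_upper_left_post: 2.0
  arm_upper_right_ant: 2.0
  arm_upper_right_post: 2.0
  arm_lower_left_ant: 1.5
  arm_lower_left_post: 1.5
  arm_lower_right_ant: 1.5
  arm_lower_right_post: 1.5
  hand_left_ant: 1.25
  hand_left_post: 1.25
  hand_right_ant: 1.25
  hand_right_post: 1.25
  thigh_left_ant: 2.75
  thigh_left_post: 2.75
  thigh_right_ant: 2.75
  thigh_right_post: 2.75
  leg_left_ant: 2.5
  leg_left_post: 2.5
  leg_right_ant: 2.5
  leg_right_post: 2.5
  foot_left_ant: 1.75
  foot_left_post: 1.75
  foot_right_ant: 1.75
  foot_right_post: 1.75
- head_ant: 8.5
  head_post: 8.5
  neck_ant: 1.0
  neck_post: 1.0
  trunk_ant: 13.0
  trunk_post: 13.0
  buttock_left: 2.5
  buttock_right: 2.5
  genitalia: 1.0
  arm_upper_left_ant: 2.0
  arm_upper_left_post: 2.0
  arm_upper_right_ant: 2.0
  arm_upper_right_post: 2.0
  arm_lower_left_ant: 1.5
  arm_lower_left_post: 1.5
  arm_lower_right_ant: 1.5
  arm_lower_right_post: 1.5
  hand_left_ant: 1.25
  hand_left_post: 1.25
  hand_right_ant: 1.25
  hand_right_post: 1.25
  thigh_left_ant: 3.25
  thigh_left_post: 3.25
  thigh_right_ant: 3.25
  thigh_right_post: 3.25
  leg_left_ant: 2.5
  leg_left_post: 2.5
  leg_right_ant: 2.5
  leg_right_post: 2.5
  foot_left_ant: 1.75
  foot_left_post: 1.75
  foot_right_ant: 1.75
  foot_right_post: 1.75
- head_ant: 6.5
  head_post: 6.5
  neck_ant: 1.0
  neck_post: 1.0
  trunk_ant: 13.0
  trunk_post: 13.0
  buttock_left: 2.5
  buttock_right: 2.5
  genitalia: 1.0
  arm_upper_left_ant: 2.0
  arm_upper_left_post: 2.0
  arm_upper_right_ant: 2.0
  arm_upper_right_post: 2.0
  arm_lower_left_ant: 1.5
  arm_lower_left_post: 1.5
  arm_lower_right_ant: 1.5
  arm_lower_right_post: 1.5
  hand_left_ant: 1.25
  hand_left_post: 1.25
  hand_right_ant: 1.25
  hand_right_post: 1.25
  thigh_left_ant: 4.0
  thigh_left_post: 4.0
  thigh_right_ant: 4.0
  thigh_right_post: 4.0
  leg_left_ant: 2.75
  leg_left_post: 2.75
  leg_right_ant: 2.75
  leg_right_post: 2.75
  foot_left_ant: 1.75
  foot_left_post: 1.75
  foot_right_ant: 1.75
  foot_right_post: 1.75
- head_ant: 5.5
  head_post: 5.5
  neck_ant: 1.0
  neck_post: 1.0
  trunk_ant: 13.0
  trunk_post: 13.0
  buttock_left: 2.5
  buttock_right: 2.5
  genitalia: 1.0
  arm_upper_left_ant: 2.0
  arm_upper_left_post: 2.0
  arm_upper_right_ant: 2.0
  arm_upper_right_post: 2.0
  arm_lower_left_ant: 1.5
  arm_lower_left_post: 1.5
  arm_lower_right_ant: 1.5
  arm_lower_right_post: 1.5
  hand_left_ant: 1.25
  hand_left_post: 1.25
  hand_right_ant: 1.25
  hand_right_post: 1.25
  thigh_left_ant: 4.25
  thigh_left_post: 4.25
  thigh_right_ant: 4.25
  thigh_right_post: 4.25
  leg_left_ant: 3.0
  leg_left_post: 3.0
  leg_right_ant: 3.0
  leg_right_post: 3.0
  foot_left_ant: 1.75
  foot_left_post: 1.75
  foot_right_ant: 1.75
  foot_right_post: 1.75
- head_ant: 4.5
  head_post: 4.5
  neck_ant: 1.0
  neck_post: 1.0
  trunk_ant: 13.0
  trunk_post: 13.0
  buttock_left: 2.5
  buttock_right: 2.5
  genitalia: 1.0
  arm_upper_left_ant: 2.0
  arm_upper_left_post: 2.0
  arm_upper_right_ant: 2.0
  arm_upper_right_post: 2.0
  arm_lower_left_ant: 1.5
  arm_lower_left_post: 1.5
  arm_lower_right_ant: 1.5
  arm_lower_right_post: 1.5
  hand_left_ant: 1.25
  hand_left_post: 1.25
  hand_right_ant: 1.25
  hand_right_post: 1.25
  thigh_left_ant: 4.5
  thigh_left_post: 4.5
  thigh_right_ant: 4.5
  thigh_right_post: 4.5
  leg_left_ant: 3.25
  leg_left_post: 3.25
  leg_right_ant: 3.25
  leg_right_post: 3.25
  foot_left_ant: 1.75
  foot_left_post: 1.75
  foot_right_ant: 1.75
  foot_right_post: 1.75
- head_ant: 3.5
  head_post: 3.5
  neck_ant: 1.0
  neck_post: 1.0
  trunk_ant: 13.0
  trunk_post: 13.0
  buttock_left: 2.5
  buttock_right: 2.5
  genitalia: 1.0
  arm_upper_left_ant: 2.0
  arm_upper_left_post: 2.0
  arm_upper_right_ant: 2.0
  arm_upper_right_post: 2.0
  arm_lower_left_ant: 1.5
  arm_lower_left_post: 1.5
  arm_lower_right_ant: 1.5
  arm_lower_right_post: 1.5
  hand_left_ant: 1.25
  hand_left_post: 1.25
  hand_right_ant: 1.25
  hand_right_post: 1.25
  thigh_left_ant: 4.75
  thigh_left_post: 4.75
  thigh_right_ant: 4.75
  thigh_right_post: 4.75
  leg_left_ant: 3.5
  leg_left_post: 3.5
  leg_right_ant: 3.5
  leg_right_post: 3.5
  foot_left_ant: 1.75
  foot_left_post: 1.75
  foot_right_ant: 1.75
  foot_right_post: 1.75

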