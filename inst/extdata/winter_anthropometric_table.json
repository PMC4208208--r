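{
  "name": "winter",
  "version": "1.0",
  "citation": "Winter, D.A. Biomechanics and Motor Control of Human Movement; segment mass fractions and CoM locations for a 9-segment model with hands merged into forearms, feet treated as ankle point masses, and head+neck merged into the trunk.",
  "units": "mass_fraction: of total body mass; length_fraction: of stature; com_fraction: of segment length from the proximal joint",
  "segments": {
    "torso_head": {"mass_fraction": 0.578, "length_fraction": 0.288, "com_fraction": 0.626},
    "upper_arm": {"mass_fraction": 0.028, "length_fraction": 0.186, "com_fraction": 0.436},
    "forearm_hand": {"mass_fraction": 0.022, "length_fraction": 0.146, "com_fraction": 0.682},
    "thigh": {"mass_fraction": 0.100, "length_fraction": 0.245, "com_fraction": 0.433},
    "shank": {"mass_fraction": 0.0465, "length_fraction": 0.246, "com_fraction": 0.433},
    "foot_point": {"mass_fraction": 0.0145}
  },
  "spans": {
    "shoulder_span_fraction": 0.259,
    "hip_span_fraction": 0.191
  }
}
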