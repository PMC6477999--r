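# Van der Burgt diagnostic criteria for Noonan syndrome, transcribed as
# feature-code mappings. Each criterion has a major (A) and minor (B)
# definition; a definition is satisfied when ANY of `any_of`, or ALL of
# `all_of`, feature codes are present. Diagnosis rule (evaluated by
# van_der_burgt_score): facies A + (>=1 other A or >=2 other B), or
# facies B + (>=2 other A or >=3 other B).
criteria:
  - id: facies
    A:
      any_of: [typical_facial_features]
    B:
      any_of: [suggestive_facial_features]
  - id: cardiac
    A:
      any_of: [pulmonary_valve_stenosis, hypertrophic_cardiomyopathy]
    B:
      any_of: [aortic_valve_stenosis, mitral_valve_incompetence,
               coarctation_of_aorta, bicuspid_aortic_valve,
               septal_defect, left_axis_deviation]
  - id: height
    A:
      any_of: [short_stature]
    B:
      any_of: [height_below_p10]
  - id: chest_wall
    A:
      any_of: [pectus_deformity]
    B:
      any_of: [broad_thorax]
  - id: family_history
    A:
      any_of: [family_history_definite_ns]
    B:
      any_of: [family_history_suggestive_ns]
  - id: other
    A:
      all_of: [mild_intellectual_disability, cryptorchidism,
               lymphatic_dysplasia]
    B:
      any_of: [mild_intellectual_disability, cryptorchidism,
               lymphatic_dysplasia]
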