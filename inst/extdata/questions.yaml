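# Default 12-question thyroid cancer extraction schema.
# answer_type: size_cm | boolean | location | count | tnm_stage |
#              histology | variant
# depends_on: conditional items are answered "not_applicable" when the
#             triggering question's answer is not the triggering value.
questions:
  - id: q1
    group: T
    answer_type: size_cm
    text: "What is the size of the primary tumor?"
  - id: q2
    group: T
    answer_type: boolean
    text: "Does the tumor extend beyond the capsule of the thyroid?"
  - id: q3
    group: T
    answer_type: location
    text: "Where is the primary cancer located (right thyroid lobe, left thyroid lobe, or isthmus)?"
  - id: q4
    group: N
    answer_type: boolean
    text: "Were any cervical lymph nodes present?"
  - id: q5
    group: N
    answer_type: count
    depends_on: {id: q4, value: yes}
    text: "If cervical lymph nodes are present, how many lymph nodes were positive for malignancy?"
  - id: q6
    group: TNM
    answer_type: tnm_stage
    text: "What is the final pathology TNM stage of the thyroid cancer?"
  - id: q7
    group: recurrence_risk
    answer_type: boolean
    text: "Is vascular invasion present?"
  - id: q8
    group: recurrence_risk
    answer_type: boolean
    text: "Is lymphatic invasion present?"
  - id: q9
    group: recurrence_risk
    answer_type: histology
    text: "What was the histology of the primary cancer?"
  - id: q10
    group: recurrence_risk
    answer_type: variant
    text: "Was there a variant of thyroid cancer such as tall cell, hobnail variant, or columnar cell variant present, indicative of a more aggressive histology?"
  - id: q11
    group: recurrence_risk
    answer_type: boolean
    text: "Was there a second thyroid cancer present?"
  - id: q12
    group: recurrence_risk
    answer_type: histology
    depends_on: {id: q11, value: yes}
    text: "If there was a second thyroid cancer present, what was the histology?"
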