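question_id,r1_llm,r2_llm,r1_r2,all_three
q1,82,84,98,82
q2,90,93,97,90
q3,99,100,99,99
q4,76,100,99,75
q5,88,88,100,88
q6,85,85,100,85
q7,99,99,100,99
q8,100,100,100,100
q9,87,87,100,87
q10,89,92,97,89
q11,82,83,99,82
q12,88,88,99,88
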