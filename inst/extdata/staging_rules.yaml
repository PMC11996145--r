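# Simplified AJCC-TNM 8th edition thyroid tumor-size cut points (cm).
# Upper bounds are inclusive: size <= t1a_max_cm -> T1a, etc.; size above
# t2_max_cm -> T3a; gross extrathyroidal extension overrides to T3b.
version: ajcc8-simplified-1
t1a_max_cm: 1
t1b_max_cm: 2
t2_max_cm: 4
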