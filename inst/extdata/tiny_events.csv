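"patient_id","visit_date","visit_type"
"p1","2014-06-15","ED"
"p2","2014-06-15","ED"
"p3","2014-06-15","inpatient"
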