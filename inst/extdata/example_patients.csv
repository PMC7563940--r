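patient_id,date1,d1_mm,date2,d2_mm,er,pr,her2,ki67
p-tn,2020-01-06,8,2020-09-04,15.1,-,-,-,30
p-her2,2020-01-06,12,2020-06-03,15.1,-,-,+,40
p-lumb2,2020-01-06,12,2020-07-03,15.1,+,-,-,25
p-lumb1,2020-01-06,12,2020-08-02,15.1,+,+,+,20
p-luma,2020-01-06,12,2020-09-11,15.1,+,+,-,8
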