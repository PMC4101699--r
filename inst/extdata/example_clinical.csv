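subject_id,GOLDCD,BMI,SEX
S001,2,-1.3066759043753629,yes
S002,4,-0.7683953250779386,yes
S003,3,-0.527108125374458,yes
S004,2,-0.021427065041624633,no
S005,2,0.6704980709962818,yes
S006,3,-0.4346170385724065,yes
S007,4,-1.1138797833128469,yes
S008,4,0.6071059948784999,no
S009,5,0.2754569687395913,yes
S010,5,1.1573470694147365,no
S011,4,-1.6824808594782557,no
S012,3,0.08731908889487436,no
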