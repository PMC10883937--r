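person_id,age,sex,region,imd_decile,died
P01,34,F,London,3,FALSE
P02,61,M,North West,7,FALSE
P03,28,F,South East,5,FALSE
P04,45,M,London,2,FALSE
P05,19,M,East of England,9,FALSE
P06,52,F,West Midlands,4,FALSE
P07,40,F,London,6,FALSE
P08,33,M,Yorkshire and The Humber,1,FALSE
P09,115,F,South West,8,FALSE
P10,27,,North East,5,FALSE
P11,70,M,East Midlands,10,TRUE
P12,8,F,London,3,FALSE
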