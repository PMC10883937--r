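person_id,coding_system,code,record_date
P01,SNOMED,100000081,2020-05-01
P02,NHS,A,2019-03-02
P04,SNOMED,100000181,2020-01-01
P06,SNOMED,100000001,2019-01-01
P06,SNOMED,100000021,2021-06-30
P07,SNOMED,100000121,2020-02-02
P09,NHS,A,2015-01-01
P11,NHS,Z,2021-01-01
P12,SNOMED,100000141,2020-08-08
P12,SNOMED,100000151,2020-08-08
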