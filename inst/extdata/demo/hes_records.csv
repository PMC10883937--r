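person_id,code,record_date
P01,H,2021-01-01
P03,4,2018-07-15
P08,Z,2019-05-05
P08,M,2017-03-03
P11,N,2015-04-04
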