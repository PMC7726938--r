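# horizon: 2019-01 2022-03
"label","effective_month","n_physicians"
"MDP ceiling","2019-01",2533
"9th cycle","2019-03",2165
"10th cycle","2019-04",2107
"11th cycle","2019-06",2106
"12th cycle","2019-08",2084
"13th cycle","2020-02",1909
"14th cycle","2020-06",1484
"15th cycle","2021-01",1427
"16th cycle","2021-12",546
"17th cycle","2022-03",320
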