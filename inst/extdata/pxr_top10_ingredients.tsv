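item	rank	positive
Sophoraflavoside IV	1	Y
Hesperidin	2	Y
Sennoside C&D	3	N
Ginsenosides Rgl	4	Y
Chlorophy II	5	N
Solanine	6	Y
Senegenic acid	7	N
Sophoraflavoside III	8	Y
Phellanmurin	9	Y
Torulosic acid	10	N
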