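gene	condition	mean
CEBPA	normal	4.724
E2F1	normal	2.475
FOXM1	normal	2.484
c-MYC	normal	1.957
hTERT	normal	2.662
CEBPA	alt	2.617
E2F1	alt	3.117
FOXM1	alt	3.115
c-MYC	alt	3.232
hTERT	alt	3.075
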