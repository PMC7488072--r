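gene	condition	mean
CEBPA	normal	4.643
E2F1	normal	3.428
FOXM1	normal	2.918
c-MYC	normal	1.842
hTERT	normal	1.874
CEBPA	telomerase	2.589
E2F1	telomerase	2.893
FOXM1	telomerase	3.020
c-MYC	telomerase	3.290
hTERT	telomerase	3.282
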