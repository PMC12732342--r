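name	category	strand	start	end	anticodon
tRNA-Ile	tRNA	J	1	64	GAU
tRNA-Gln	tRNA	N	62	127	UUG
tRNA-Met	tRNA	J	133	198	CAU
nad2	PCG	J	199	1174
tRNA-Trp	tRNA	J	1175	1236	UCA
tRNA-Cys	tRNA	N	1229	1296	GCA
tRNA-Tyr	tRNA	N	1300	1364	GUA
cox1	PCG	J	1366	2896
tRNA-Leu2	tRNA	J	2897	2964	UAA
cox2	PCG	J	2965	3639
tRNA-Lys	tRNA	J	3642	3714	CUU
tRNA-Asp	tRNA	J	3715	3778	GUC
atp8	PCG	J	3779	3937
atp6	PCG	J	3918	4570
cox3	PCG	J	4571	5355
tRNA-Gly	tRNA	J	5356	5419	UCC
nad3	PCG	J	5420	5773
tRNA-Ala	tRNA	J	5774	5836	UGC
tRNA-Arg	tRNA	J	5836	5899	UCG
tRNA-Asn	tRNA	J	5900	5963	GUU
tRNA-Ser1	tRNA	J	5963	6022	GCU
tRNA-Glu	tRNA	J	6030	6095	UUC
repeat region	repeat_region	J	6096	6369
tRNA-Phe	tRNA	N	6370	6433	GAA
nad5	PCG	N	6434	8155
tRNA-His	tRNA	N	8223	8283	GUG
nad4	PCG	N	8284	9607
nad4l	PCG	N	9601	9891
tRNA-Thr	tRNA	J	9893	9954	UGU
tRNA-Pro	tRNA	N	9957	10022	UGG
nad6	PCG	J	10024	10515
cytb	PCG	J	10519	11632
tRNA-Ser2	tRNA	J	11633	11697	UGA
nad1	PCG	N	11708	12643
tRNA-Leu1	tRNA	N	12644	12708	UAG
rrnL	rRNA	N	12709	13966
tRNA-Val	tRNA	N	13967	14028	UAC
rrnS	rRNA	N	14029	14804
control region	control_region	J	14805	15720
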