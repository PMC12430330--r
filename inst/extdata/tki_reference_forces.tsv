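# Published specific (F_i) and non-specific (F_0) forces between HSA
# molecules in the presence of six tyrosine kinase inhibitors, per applied
# electric field strength; Poisson step analysis of >300 force-distance
# curves per condition, reported as mean +/- SD (pN).
drug	field_mV_mm	f_i_pN	f_i_sd	f_0_pN	f_0_sd
imatinib	0	35.1	0.5	101	2
imatinib	20	33.4	0.4	90	2
imatinib	40	31.6	0.2	80	1
imatinib	60	28.9	0.3	71	2
imatinib	80	27.2	0.5	62	2
imatinib	100	25.2	0.3	52	1
bosutinib	0	29.1	0.4	114	1
bosutinib	20	27.0	0.4	103.7	0.9
bosutinib	40	25.8	0.6	93	2
bosutinib	60	24.7	0.2	81	1
bosutinib	80	23.2	0.3	72	2
bosutinib	100	21.3	0.7	64	1
dasatinib	0	37.3	0.8	112	1
dasatinib	20	35.6	0.7	103	1
dasatinib	40	32.7	0.7	95	2
dasatinib	60	30.3	0.5	85	1
dasatinib	80	27.5	0.4	75	2
dasatinib	100	26.0	0.8	67	2
nilotinib	0	34.1	0.6	103	1
nilotinib	20	32.0	0.7	91.4	0.9
nilotinib	40	30.1	0.5	81	2
nilotinib	60	28.2	0.3	70	2
nilotinib	80	26.8	0.4	59	1
nilotinib	100	24.5	0.5	49	1
ponatinib	0	40.4	0.7	108	1
ponatinib	20	36.9	0.5	100	1
ponatinib	40	34.4	0.6	92.6	0.9
ponatinib	60	31.5	0.9	84	2
ponatinib	80	28.9	0.5	76	3
ponatinib	100	25.4	0.6	67	1
radotinib	0	42.1	0.6	116	2
radotinib	20	37.7	0.5	103	1
radotinib	40	34.6	0.4	93	1
radotinib	60	31.2	0.7	81	2
radotinib	80	27.4	0.7	68	2
radotinib	100	23.6	0.4	57	2
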