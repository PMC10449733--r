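id	region	quantity	observed	predicted	rpe_printed
ID2	tumor	auc	3.32	2.95	-11
ID3	tumor	auc	2.09	2.67	28
ID4	tumor	auc	5.29	4.05	-23
ID5	tumor	auc	4.69	2.89	-38
ID6	tumor	auc	1.38	0.825	-40
ID7	tumor	auc	2.80	3.06	9
ID8	tumor	auc	2.94	3.16	8
ID9	tumor	auc	1.76	1.50	-14
ID10	tumor	auc	2.59	2.60	0
ID3	kidney	auc	0.520	0.533	4
ID4	kidney	auc	0.634	0.680	14
ID5	kidney	auc	0.334	0.469	41
ID6	kidney	auc	0.902	0.408	-53
ID7	kidney	auc	0.564	0.479	-12
ID8	kidney	auc	0.443	0.410	-10
ID9	kidney	auc	0.764	0.496	-32
ID10	kidney	auc	0.621	0.426	-32
ID2	tumor	dose	24.4	21.3	-13
ID3	tumor	dose	14.4	17.4	21
ID4	tumor	dose	29.3	19.6	-33
ID5	tumor	dose	38.3	18.7	-51
ID6	tumor	dose	8.67	5.62	-35
ID7	tumor	dose	34.4	25.5	-26
ID8	tumor	dose	19.5	28.1	44
ID9	tumor	dose	12.4	12.1	-3
ID10	tumor	dose	27.7	21.5	-23
ID3	kidney	dose	3.12	2.57	33
ID4	kidney	dose	2.21	2.57	-18
ID5	kidney	dose	1.19	2.69	21
ID6	kidney	dose	5.38	2.17	82
ID7	kidney	dose	3.92	2.26	-58
ID8	kidney	dose	3.79	2.81	-28
ID9	kidney	dose	4.41	2.51	-34
ID10	kidney	dose	3.71	2.75	-38
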