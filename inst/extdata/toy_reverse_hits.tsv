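c01	REF1	90	500	10	0	1	500	1	500	1e-60	300
c01	KINX	40	400	100	2	1	400	1	400	1e-10	120
c02	REF1	90	500	10	0	1	500	1	500	1e-60	300
c03	REF2	88	480	12	0	1	480	1	480	1e-55	290
c04	KINX	80	450	30	1	1	450	1	450	1e-58	300
c04	REF1	70	450	50	1	1	450	1	450	1e-50	250
c05	REF1	85	480	20	0	1	480	1	480	1e-55	300
c05	KINX	85	480	20	0	1	480	1	480	1e-55	300
c06	REF1	90	430	15	1	1	430	44	470	1e-52	280
c07	REF1	90	399	10	0	1	399	1	399	1e-45	260
c08	REF1	90	416	10	0	1	416	85	500	1e-48	270
c09	REF1	90	417	10	0	1	417	84	500	1e-48	270
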