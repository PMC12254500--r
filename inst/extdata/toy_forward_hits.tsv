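c01	REF1	90	500	10	0	1	500	1	500	1e-50	400
c02	REF1	90	500	10	0	1	500	1	500	1e-20	400
c03	REF1	90	500	10	0	1	500	1	500	1e-28	400
c04	REF1	90	500	10	0	1	500	1	500	1e-50	400
c05	REF1	90	500	10	0	1	500	1	500	1e-50	400
c06	REF1	90	217	10	0	1	217	44	260	1e-50	400
c06	REF1	90	231	10	0	1	231	240	470	1e-50	400
c07	REF1	90	399	10	0	1	399	1	399	1e-50	400
c08	REF1	90	416	10	0	1	416	85	500	1e-50	400
c09	REF1	90	417	10	0	1	417	84	500	1e-50	400
c10	REF1	90	500	10	0	1	500	1	500	1e-50	400
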