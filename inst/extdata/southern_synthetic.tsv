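# Synthetic Southern-blot densitometry series (constructed, not measured):
# intensities are invented so that the donor-normalized, t0-normalized
# recipient ratios equal the published summary curve for each enzyme
# (maximum cleavage 82% for ZFN and 48% for I-SceI at 3 h; 16% and 10% of
# broken molecules repaired between 3 h and 6 h).
enzyme	time_h	recipient_intensity	donor_intensity
ZFN	0	900	1000
ZFN	0.75	693	1100
ZFN	1.5	384.75	950
ZFN	3	170.1	1050
ZFN	6	280.08	1000
ZFN	12	661.5	980
I-SceI	0	1100	1000
I-SceI	0.75	953.7	1020
I-SceI	1.5	762.3	990
I-SceI	3	577.72	1010
I-SceI	6	624.8	1000
I-SceI	12	853.36	970
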