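pos	p_tis	p_tts	p_none
30	3.314e-02	1.099e-04	9.667e-01
31	6.293e-02	1.729e-04	9.368e-01
32	4.755e-02	1.027e-04	9.523e-01
216	1.005e-05	1.334e-01	8.666e-01
217	1.341e-04	9.223e-02	9.076e-01
218	3.026e-05	1.171e-01	8.827e-01
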