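feature_id,mz,rt_min,intensity,polarity,ri
F01,205.0970,5.03,1000000,pos,472
F02,377.1459,9.69,200000,pos,586
F03,208.0967,11.26,50000,pos,634
F04,139.0389,6.51,300000,pos,513
F05,137.0250,6.53,250000,neg,513
F06,375.1306,9.69,150000,neg,586
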