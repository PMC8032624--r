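# SYNTHETIC reference dataset - not measured data. Reconstructed rat in vivo
# blood-AChE inhibition landmarks for ordinal comparison of predicted
# dose-response curves, anchored on printed regulatory values: a reported rat
# RBC-AChE BMDL10 of 1.99 mg/kg bw (10% inhibition near ~2-6 mg/kg) and a rat
# brain-AChE NOAEL of 100 mg/kg bw. Intermediate points interpolate a
# log-dose sigmoid through those anchors. Use only for qualitative checks.
dose_mg_kg,inhibition_pct
2,10
6,22
15,35
30,50
60,65
100,75
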