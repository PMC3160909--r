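# Seven-way overlap partition of expressed-gene sets at the three limb
# stages, transcribed from the published figure legend.  The E13.5-only
# cell (244) is the printed "gained at E13.5" count (899) minus the subset
# still expressed at E15.5 (655).
cell	count
E11.5&E13.5&E15.5	9099
E11.5	297
E13.5	244
E15.5	871
E11.5&E13.5	475
E11.5&E15.5	203
E13.5&E15.5	655
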