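parameter	value
hairpin_3	5.40
hairpin_4	5.60
hairpin_5	5.70
hairpin_6	5.40
hairpin_7	6.00
hairpin_8	5.50
hairpin_9	6.40
hairpin_10	6.50
hairpin_11	6.60
hairpin_12	6.70
hairpin_13	6.80
hairpin_14	6.90
hairpin_15	6.90
hairpin_16	7.00
hairpin_17	7.10
hairpin_18	7.10
hairpin_19	7.20
hairpin_20	7.20
hairpin_21	7.30
hairpin_22	7.30
hairpin_23	7.40
hairpin_24	7.40
hairpin_25	7.50
hairpin_26	7.50
hairpin_27	7.50
hairpin_28	7.60
hairpin_29	7.60
hairpin_30	7.70
terminal_au	0.50
closing_gc	-0.50
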