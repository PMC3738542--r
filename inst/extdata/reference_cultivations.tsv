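run	strain	sampling_hour	sampling_cdm_g_per_L	growth_rate_per_h	end_cdm_g_per_L	max_acetate_g_per_L	early_sample
HMS1	HMS174	9	10.02	0.47	13.33	6.25	FALSE
HMS2	HMS174	9	8.49	0.40	14.41	6.00	FALSE
HMS3	HMS174	9	9.81	0.43	13.43	5.54	FALSE
RV1	RV308	9	11.87	0.50	15.16	6.01	FALSE
RV2	RV308	9	12.38	0.47	14.88	4.70	FALSE
RV3	RV308	9	11.35	0.46	17.49	5.89	FALSE
BL1	BL21	5.25	11.07	0.73	17.74	1.37	FALSE
BL2	BL21	5.25	9.58	0.74	15.60	1.18	TRUE
BL3	BL21	5.25	10.32	0.73	17.9	1.34	FALSE
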