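metric	mean_baseline	sd_baseline	mean_treatment	sd_treatment	direction	improvement_pct	t_value	n	effect_d
tasks_completed	3.2	0.6	5.3	0.8	higher	65.6	6.84	8	2.42
spatial_error_mm	0.39	0.07	0.27	0.04	lower	30.8	5.12	8	1.81
efficiency	68.4	5.2	82.8	3.1	higher	21.1	7.93	8	2.80
nasa_tlx	72.1	6.8	53.5	5.5	lower	25.8	NA	8	NA
success_rate	88.8	4.1	95.6	2.9	higher	7.7	4.21	8	1.49
precision	6.4	0.8	8.1	0.6	higher	26.6	5.67	8	2.00
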