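metric	mean_baseline	mean_treatment	direction	improvement_pct
mental_demand	84	65	lower	-22.6
physical_demand	85	70	lower	-17.6
temporal_demand	75	64	lower	-14.7
performance	60	75	higher	25.0
effort	72	58	lower	-19.4
frustration	52	35	lower	-32.7
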