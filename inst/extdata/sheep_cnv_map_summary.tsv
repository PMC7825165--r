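group	class	count	n_duplication	n_deletion	n_both	total_length_mb	n_individuals
AMS_no	cnv	427844	12657	415187	NA	1874.08	8
AMS_horn	cnv	428669	12545	416124	NA	1868.48	8
CMS_horn	cnv	444221	12429	431792	NA	1881.06	8
AHS_no	cnv	446870	12220	434650	NA	1883.50	8
AMS_no	cnvr	5233	705	4518	10	13.50	8
AMS_horn	cnvr	5297	725	4567	5	14.03	8
CMS_horn	cnvr	5394	694	4689	11	14.14	8
AHS_no	cnvr	5441	698	4735	8	14.39	8
cohort	cnvr	7228	861	6345	22	56.06	32
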