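symbol	inheritance	missense_z	benign_nonvus_missense	total_nonvus_missense	lof_mechanism	bp1_z_rule
SERPINA6	AR	-0.662	NA	NA	NA	TRUE
TYR	AR	NA	NA	NA	TRUE	FALSE
USH2A	AR	NA	196	529	TRUE	FALSE
CELSR1	AD	NA	33	33	NA	FALSE
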