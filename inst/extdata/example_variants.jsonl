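{"sample_id":"S_SERPINA6","panel":"ENDO","annotation":"SERPINA6:NM_001756.4:c.1165G>A","hgvs_p":"p.(Asp389Asn)","consequence":"missense","zygosity":"het","scores":{"revel":0.518,"cadd_phred":24.78,"rank_scores":{"DANN":0.9,"EigenPC":0.9,"FATHMM":0.9,"LRT":0.9,"MCAP":0.9,"MetaLR":0.9,"MetaSVM":0.9,"MutPred":0.9,"MutationAssessor":0.9,"MutationTaster":0.9,"PROVEAN":0.9,"Polyphen2HDIV":0.4,"Polyphen2HVAR":0.4,"SIFT":0.4,"VEST3":0.4}},"population":{"maf_by_source":{"gnomAD":1e-05},"gnomad_hom_count":0,"coverage_ok":true},"gene":{"symbol":"SERPINA6","inheritance":"AR","missense_z":-0.662,"bp1_z_rule":true},"clinvar":{"classification":"VUS","stars":2,"n_submissions":5},"upstream_calls":[{"criterion":"BP4","met":true,"strength":"Strong","rationale":"upstream meta-predictor call","source":"upstream"},{"criterion":"PM2","met":true,"strength":"Supporting","rationale":"GnomAD genomes homozygous allele count = 0 is less than 2","source":"upstream"},{"criterion":"PP5","met":true,"strength":"Supporting","rationale":"ClinVar classifies this variant as Uncertain Significance, 2 stars","source":"upstream"}]}
{"sample_id":"S_TYR","panel":"ALBINISM","annotation":"TYR:NM_000372.5:c.1586del","hgvs_p":"p.(Leu529Tyrfs*7)","consequence":"frameshift","zygosity":"het","scores":{"rank_scores":[]},"population":{"maf_by_source":[],"coverage_ok":true},"gene":{"symbol":"TYR","inheritance":"AR","lof_mechanism":true,"bp1_z_rule":false},"lof":{"lof_type":"frameshift","nmd_predicted":false,"exon_in_relevant_transcript":true,"lof_frequent_in_population":false,"fraction_protein_removed":0.0019,"truncated_region_critical":false,"pathogenic_variants_in_truncated_region":0},"upstream_calls":[]}
{"sample_id":"S_USH2A","panel":"USHER","annotation":"USH2A:NM_206933.4:c.5213T>C","hgvs_p":"p.(Phe1738Ser)","consequence":"missense","zygosity":"het","scores":{"revel":0.767,"cadd_phred":28.3,"rank_scores":{"DANN":0.9,"EigenPC":0.9,"FATHMM":0.9,"LRT":0.9,"MCAP":0.9,"MetaLR":0.9,"MetaSVM":0.9,"MutPred":0.9,"MutationAssessor":0.9,"MutationTaster":0.9,"PROVEAN":0.9,"Polyphen2HDIV":0.9,"Polyphen2HVAR":0.9,"SIFT":0.9,"VEST3":0.4}},"population":{"maf_by_source":[],"coverage_ok":true},"gene":{"symbol":"USH2A","inheritance":"AR","benign_nonvus_missense":196,"total_nonvus_missense":529,"lof_mechanism":true,"bp1_z_rule":false},"upstream_calls":[{"criterion":"PP4","met":true,"strength":"Supporting","rationale":"phenotype (Usher syndrome) highly specific for the gene","source":"upstream"}]}
{"sample_id":"S_USH2A","panel":"USHER","annotation":"USH2A:NM_206933.4:c.2299del","hgvs_p":"p.(Glu767Serfs*21)","consequence":"frameshift","zygosity":"het","scores":{"rank_scores":[]},"population":{"maf_by_source":{"gnomAD":0.0008},"coverage_ok":true},"gene":{"symbol":"USH2A","inheritance":"AR","benign_nonvus_missense":196,"total_nonvus_missense":529,"lof_mechanism":true,"bp1_z_rule":false},"lof":{"lof_type":"frameshift","nmd_predicted":true,"exon_in_relevant_transcript":true,"lof_frequent_in_population":false,"fraction_protein_removed":0.85},"upstream_calls":[{"criterion":"PM2","met":true,"strength":"Supporting","rationale":"extremely low frequency for recessive gene","source":"upstream"},{"criterion":"PS4","met":true,"strength":"Strong","rationale":"established founder variant with greatly increased prevalence in affected individuals","source":"upstream"}]}
{"sample_id":"S_CELSR1","panel":"LYMPH","annotation":"CELSR1:NM_014246.4:c.5165G>A","hgvs_p":"p.(Arg1722Gln)","consequence":"missense","zygosity":"het","scores":{"revel":0.723,"cadd_phred":29.1,"rank_scores":{"DANN":0.9,"EigenPC":0.9,"FATHMM":0.9,"LRT":0.9,"MCAP":0.9,"MetaLR":0.9,"MetaSVM":0.9,"MutPred":0.9,"MutationAssessor":0.9,"MutationTaster":0.9,"PROVEAN":0.9,"Polyphen2HDIV":0.9,"Polyphen2HVAR":0.9,"SIFT":0.4,"VEST3":0.4}},"population":{"maf_by_source":{"gnomAD":8e-06},"gnomad_allele_count":2,"coverage_ok":true},"gene":{"symbol":"CELSR1","inheritance":"AD","benign_nonvus_missense":33,"total_nonvus_missense":33,"bp1_z_rule":false},"upstream_calls":[{"criterion":"PM2","met":true,"strength":"Supporting","rationale":"GnomAD genomes allele count = 2 is less than 5 for AD gene CELSR1","source":"upstream"}]}
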