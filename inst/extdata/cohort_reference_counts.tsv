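cohort	statistic	value
AD_FBS	n_families_screened	251
AD_FBS	n_individuals_screened	1055
AD_FBS	n_families	197
AD_FBS	n_individuals	926
AD_FBS	n_affected	545
AD_FBS	n_unaffected	381
AD_FBS	n_families_rare_complete	38
AD_FBS	n_families_apoe_only	64
AD_FBS	n_families_unexplained	99
AD_FBS	n_distinct_variants_complete	46
AD_FBS	n_distinct_genes_complete	32
EFIGA	n_families_screened	271
EFIGA	n_individuals_screened	1481
EFIGA	n_families	214
EFIGA	n_individuals	1340
EFIGA	n_affected	793
EFIGA	n_unaffected	547
EFIGA	n_families_rare_complete	34
EFIGA	n_families_apoe_only	29
EFIGA	n_families_unexplained	149
EFIGA	n_distinct_variants_complete	40
EFIGA	n_distinct_genes_complete	32
COMBINED	n_families	411
COMBINED	n_individuals	2266
COMBINED	n_families_rare_complete	72
COMBINED	n_families_apoe_only	93
COMBINED	n_families_unexplained	248
COMBINED	n_variant_rows_complete	86
COMBINED	n_variants_in_ld	33
COMBINED	n_variants_ld_denominator	76
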