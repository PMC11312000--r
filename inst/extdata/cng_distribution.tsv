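# Reference ALK copy-number-gain category counts per concordance group
# (sample-level categories from break-apart probe enumeration).
group	cng_category	n_cases
positive_discordant	<=3	12
positive_discordant	4-6	8
positive_discordant	7-9	6
positive_discordant	10+	7
negative_discordant	<=3	11
negative_discordant	4-6	2
negative_discordant	7-9	1
negative_discordant	10+	3
positive_concordant	<=3	129
positive_concordant	4-6	40
positive_concordant	7-9	19
positive_concordant	10+	1
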