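# Reference discordant and concordant cases with NGS results (multi-component
# tumors represented by the reported dominant component; NA = no ALK fusion
# called).
case_id	sex	age	fish_status	percent_rearranged	pattern	ihc_status	alk_fusion_partner
1	M	69	POSITIVE	26	translocation+inversion	negative	NA
2	M	60	POSITIVE	68	inversion	negative	NA
3	M	53	POSITIVE	64	inversion	negative	EML4
4	M	70	POSITIVE	44	five_prime_deletion+translocation	negative	NA
5	M	68	POSITIVE	30	translocation+interstitial_deletion	negative	NA
6	F	70	POSITIVE	26	inversion	negative	NA
7	M	64	POSITIVE	18	five_prime_deletion+inversion	negative	NA
8	F	75	POSITIVE	17	five_prime_deletion+translocation+inversion	negative	NA
9	M	78	POSITIVE	60	five_prime_deletion	negative	NA
10	M	63	POSITIVE	16	translocation+inversion	negative	NA
11	F	79	NEGATIVE	4	NA	negative	NA
12	F	77	NEGATIVE	4	NA	positive	EML4
13	F	71	NEGATIVE	2	NA	positive	CSFT3
14	F	56	POSITIVE	50	inversion	positive	EML4
15	F	73	POSITIVE	48	interstitial_deletion+inversion	positive	EML4
16	M	48	POSITIVE	62	five_prime_deletion+interstitial_deletion	positive	HIP1
17	F	64	POSITIVE	90	interstitial_deletion	positive	EML4
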