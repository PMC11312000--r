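# Reference distribution of rearrangement-pattern combinations among
# FISH-positive samples retested with the tri-color ALK/EML4 fusion probe,
# by IHC concordance group and by whether any single signal variant reached
# the 15% positivity cut-off (subthreshold = 1: composite positives).
# Combinations are ordered predominant class first.
group	combination	subthreshold	n_samples
discordant	inversion	1	5
discordant	inversion	0	5
discordant	five_prime_deletion	0	2
discordant	interstitial_deletion+inversion	0	3
discordant	five_prime_deletion+inversion	1	2
discordant	five_prime_deletion+translocation	0	4
discordant	interstitial_deletion+translocation	1	1
discordant	translocation+inversion	1	1
discordant	inversion+translocation	1	3
discordant	five_prime_deletion+translocation+inversion	1	1
discordant	five_prime_deletion+translocation+inversion	0	2
concordant	inversion	1	2
concordant	inversion	0	131
concordant	interstitial_deletion	0	4
concordant	interstitial_deletion+inversion	0	21
concordant	five_prime_deletion+interstitial_deletion	0	4
concordant	translocation+interstitial_deletion	0	1
concordant	interstitial_deletion+translocation	0	1
concordant	translocation+inversion	0	3
concordant	five_prime_deletion+translocation+inversion	0	1
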