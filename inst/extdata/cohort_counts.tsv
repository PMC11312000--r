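# Reference cohort concordance counts: simultaneous IHC + FISH ALK testing,
# before and after the IHC reevaluation (dot-like) step.
key	value
n_tested	2813
n_failed	130
n_analyzed	2683
pos_conc_initial	184
pos_disc_initial	38
ihc_repeated	9
dot_like_reclassified	5
pos_conc_final	189
pos_disc_final	33
neg_disc	17
neg_conc	2444
fish_positive	222
fish_negative	2461
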