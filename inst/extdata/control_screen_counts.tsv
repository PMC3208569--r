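# Population-control screen of the three perfectly-segregating candidates:
# heterozygous carriers observed among 1,600 ethnically matched controls
# (3,200 chromosomes). No homozygous carriers were observed.
gene	n_controls	het_carriers	hom_carriers
PDCD6IP	1600	16	0
LIPJ	1600	8	0
DNAJC5	1600	0	0
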