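# Per-sample attrition counts for the coding single-nucleotide-substitution
# filtering cascade in the discovery family (two affected, one unaffected
# sibling control, sequenced on one flow cell). Stage counts after the first
# are joint (per variant set), so they are recorded on the first row only.
sample	status	total_coding_sns	nonsynonymous_sns	sns_after_filtering	sns_in_both_cases	sns_unique_to_cases	sns_after_panel
affected_1	affected	38142	9202	674	96	24	19
affected_2	affected	38276	9285	636	NA	NA	NA
control	unaffected	38120	9177	711	NA	NA	NA
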