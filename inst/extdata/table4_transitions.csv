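# Yearly stage transition probabilities for standard of care (derived in the
# source from 5-year progression percentages). stay + progress = 1 per stage,
# before mortality is applied.
stage,p_stay,p_progress
early,0.915,0.085
moderate,0.876,0.124
advanced,0.814,0.186
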