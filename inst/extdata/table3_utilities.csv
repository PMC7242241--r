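# Stage utility weights (HUI-3, German POAG sample). The blindness utility was
# derived in the source by least-squares extrapolation of the three POAG-stage
# utilities; the package recomputes it (extrapolate_blind_utility) and the row
# here carries the published SD for probabilistic sampling.
state,utility,utility_sd,source
early,0.85,0.15,observed
moderate,0.75,0.23,observed
advanced,0.58,0.32,observed
blind,0.46,0.40,least_squares
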