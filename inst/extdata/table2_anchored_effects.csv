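# Published anchored 1-year IOP changes from baseline (mmHg) with 95% CIs, as
# estimated by adjusted indirect comparison against the common cataract-alone
# arm. Used for (a) the default anchor (cataract_alone row) and (b) normal
# effect-uncertainty parameters in the probabilistic sensitivity analysis,
# because the underlying per-trial standard errors were never published.
strategy,mean,ci_low,ci_high,k,i2
cataract_alone,-2.05,-3.38,-0.72,4,81
one_tmbs,-3.15,-5.66,-0.64,2,39
two_tmbs,-4.85,-7.71,-1.99,1,NA
is,-2.25,-4.87,0.37,1,NA
one_or_two_tmbs,-3.87,-6.66,-1.08,3,97
migs_class,-3.49,-5.52,-1.46,4,97
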