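# Randomized trials of MIGS combined with cataract surgery vs cataract surgery
# alone in POAG: per-arm IOP summaries (mmHg), baseline and year 1.
# Arm sizes and SDs of change were not published; n is left blank.
# Note: the Craven control-arm year-1 entry was printed as "17. (3.1)" in the
# source table; it is encoded here as 17.0 mmHg.
strategy,study_id,arm,n,mean_baseline,sd_baseline,mean_followup,sd_followup
one_tmbs,Craven2012,intervention,,18.6,3.4,17.0,2.8
one_tmbs,Craven2012,control,,17.9,3.0,17.0,3.1
one_tmbs,Fea2010,intervention,,17.8,2.7,14.7,1.3
one_tmbs,Fea2010,control,,16.7,3.0,15.6,1.1
two_tmbs,FernandezBarrientos2010,intervention,,24.2,1.6,17.6,2.8
two_tmbs,FernandezBarrientos2010,control,,23.6,1.5,19.8,2.3
is,Pfeiffer2015,intervention,,18.9,3.3,16.1,3.0
is,Pfeiffer2015,control,,18.6,3.8,16.0,2.8
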