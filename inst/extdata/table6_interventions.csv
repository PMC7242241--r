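# One-off intervention costs (2019 EUR): MIGS surgical procedure (including
# postoperative monitoring/treatment) and cataract surgery. Totals are
# recomputed by the package.
intervention,migs_procedure,cataract_surgery
cataract_alone,0,224.84
one_migs_device,413.58,224.84
two_migs_devices,712.50,224.84
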