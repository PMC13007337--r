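group,mean_total,sem,n_preparations
surface,61.4,5.51,16
cave,73.6,9.3,16
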