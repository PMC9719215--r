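name	klass	cutoff
RT_core	shared	80
RNaseH	shared	80
AP	caulimovirid_associated	80
MP	caulimovirid_associated	80
zf_CCHC	shared	70
integrase	te_specific	80
transposase	te_specific	80
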