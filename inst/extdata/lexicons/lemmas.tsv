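running	run
ran	run
runs	run
prayers	pray
praying	pray
prayed	pray
fevers	fever
coughing	cough
coughs	cough
breathing	breathe
masks	mask
cases	case
deaths	death
hospitals	hospital
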