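species	peaks	batch
B. peregrina	75.26	run3
P. dux	77.40	run3
S. princeps	77.20	run3
P. misera	76.96	run3
P. sericea	77.14	run3
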