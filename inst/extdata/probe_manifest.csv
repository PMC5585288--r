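species,stain,animals,probes
rat,MAP2,3,323
macaque,MAP2,3,361
rat,PCP2,1,113
macaque,PCP2,1,244
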