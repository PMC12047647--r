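name,sigma,comment
scalp,0.4,low-frequency scalp/skin conductivity S/m
skull,0.01,compact bone average S/m
csf,1.8,cerebrospinal fluid S/m
gm,0.3,gray matter S/m
wm,0.15,white matter (isotropic fallback) S/m
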