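# folded abbreviation forms whose trailing period never ends a sentence
dr
prof
mevr
dhr
mme
mlle
mr
o.a
d.w.z
e.g
i.e
resp
cfr
ca
nr
art
evt
t.h.v
vs
afd
dd
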