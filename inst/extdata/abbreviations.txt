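# tokens before a bare "." that do not end a sentence
dr
mr
mrs
ms
st
jr
sr
prof
vs
etc
approx
dept
fig
eg
ie
al
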