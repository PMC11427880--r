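# anger words
angry
anger*
mad
madder
hate
hates
hated
hating
annoy*
furious
fury
rage*
frustrat*
irritat*
outrage*
resent*
hostile
hostility
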