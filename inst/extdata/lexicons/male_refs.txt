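# male references
he
him
his
himself
man
men
male*
boy*
guy
guys
father*
dad
dads
brother*
son
sons
husband
husbands
uncle*
grandfather*
grandpa*
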