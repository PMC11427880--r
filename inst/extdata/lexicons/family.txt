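# family references
family*
mother*
mom
moms
mommy
dad
dads
daddy
father*
brother*
sister*
husband
husbands
wife
wives
son
sons
daughter*
parent*
grandma*
grandpa*
grandmother*
grandfather*
aunt
aunts
uncle*
cousin*
sibling*
baby
babies
kid
kids
child
children
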