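# female references
she
her
hers
herself
woman
women
female*
girl*
lady
ladies
mother*
mom
mommy
sister*
daughter*
wife
wives
aunt
aunts
grandmother*
grandma*
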