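# interrogative words; closed set, overridable. Contracted forms
# ("what's") match through the contraction-expansion table.
who
whom
whose
what
which
where
when
why
how
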