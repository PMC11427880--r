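# past temporal focus
was
were
had
did
been
ago
yesterday
before
earlier
previously
formerly
last
went
gone
got
said
told
happened
used
started
began
begun
took
taken
felt
gave
given
came
saw
seen
diagnosed
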