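# present temporal focus
is
am
are
be
being
now
today
currently
presently
nowadays
have
has
do
does
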