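# impersonal / indefinite pronouns
it
its
itself
this
that
these
those
anything
anyone
anybody
something
someone
somebody
nothing
nobody
none
everything
everyone
everybody
other
others
another
what
whatever
which
whichever
there
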