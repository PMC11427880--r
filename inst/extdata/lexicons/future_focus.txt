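# future temporal focus
will
shall
going
gonna
soon
tomorrow
future
upcoming
eventually
later
plan
plans
planning
hope
hopes
hoping
expect*
predict*
anticipat*
may
might
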