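# positive emotion words
good
great
better
best
happy
happi*
happier
love
loves
loved
loving
hope
hopes
hoping
hopeful*
glad
thank*
nice
nicer
wonderful*
amazing
awesome
relief
relieved
comfort*
support*
calm*
safe
safely
grateful*
joy
joyful
enjoy*
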