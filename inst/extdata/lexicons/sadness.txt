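# sadness words
sad
sadness
sadly
cry
cries
cried
crying
depress*
grief
griev*
hopeless*
lonely
loneliness
miserable
misery
sorrow*
heartbroken
tear
tears
tearful
unhappy
mourn*
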