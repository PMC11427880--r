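# overall affect: union of positive and negative emotion words
afraid
amazing
anger*
angry
annoy*
anxiety
anxious*
apprehensi*
awesome
awful
bad
best
better
calm*
comfort*
cried
cries
cry
crying
depress*
dread*
enjoy*
fear*
frustrat*
furious
fury
glad
good
grateful*
great
grief
griev*
happi*
happier
happy
hate
hated
hates
hating
heartbroken
hope
hopeful*
hopeless*
hopes
hoping
horribl*
horrible
hostile
hostility
hurt
hurting
hurts
irritat*
joy
joyful
loneliness
lonely
love
loved
loves
loving
mad
madder
miserable
misery
mourn*
nasty
nervous*
nice
nicer
outrage*
painful*
panic*
rage*
relief
relieved
resent*
sad
sadly
sadness
safe
safely
scare
scared
scary
sorrow*
stress*
stressed
suffer*
support*
tear
tearful
tears
tense
tension
terrible
terrified
terrify*
thank*
ugly
uneasy
unhappy
wonderful*
worried
worries
worry
worrying
worse
worst
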