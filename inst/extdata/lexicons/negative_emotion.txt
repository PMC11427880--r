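# negative emotion: superset of anxiety, anger and sadness words
# plus general negative terms
bad
worse
worst
awful
terrible
horrible
horribl*
hurt
hurts
hurting
suffer*
nasty
ugly
painful*
worry
worries
worried
worrying
anxious*
anxiety
nervous*
afraid
fear*
scared
scary
scare
panic*
stress*
stressed
tense
tension
terrified
terrify*
dread*
uneasy
apprehensi*
angry
anger*
mad
madder
hate
hates
hated
hating
annoy*
furious
fury
rage*
frustrat*
irritat*
outrage*
resent*
hostile
hostility
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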