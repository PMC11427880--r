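# anxiety words
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
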