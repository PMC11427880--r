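# body references
body
bodies
kidney*
renal
heart*
blood
liver
lung*
stomach
skin
bone*
muscle*
head
arm
arms
leg
legs
back
eye
eyes
ear
ears
bladder
urine
urinary
organ
organs
brain
chest
abdomen
abdominal
hand
hands
foot
feet
face
hair
throat
neck
vein*
nerve*
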