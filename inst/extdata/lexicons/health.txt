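# health references
health*
doctor*
nurse*
hospital*
clinic*
medical
medicine*
medication*
drug*
pill*
symptom*
diagnos*
treat*
therapy
therapies
therapist*
surgery
surgeries
surgeon*
disease*
illness*
sick*
pain*
ache*
infection*
dialysis
transplant*
chronic
cancer*
diabet*
pressure
prescri*
dose*
dosage*
checkup*
flu
fever*
nausea*
fatigue*
injur*
wound*
healing
heal
heals
healed
patient*
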