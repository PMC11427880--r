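# social processes: people words and interaction verbs,
# includes family, friend and gendered references
people
person
community
communities
talk*
talking
share*
sharing
tell
tells
telling
told
ask
asks
asked
asking
help*
advice
advise*
meet
meets
meeting
call
calls
called
calling
social*
group*
everyone
anybody
somebody
partner*
relationship*
aunt
aunts
babies
baby
boy*
brother*
buddies
buddy
child
children
colleague*
companion*
cousin*
coworker*
dad
daddy
dads
daughter*
family*
father*
female*
friend*
girl*
grandfather*
grandma*
grandmother*
grandpa*
guy
guys
he
her
hers
herself
him
himself
his
husband
husbands
kid
kids
ladies
lady
male*
man
men
mom
mommy
moms
mother*
neighbor*
neighbour*
pal
pals
parent*
roommate*
she
sibling*
sister*
son
sons
uncle*
wife
wives
woman
women
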