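# packaged syllable dictionary: health vocabulary and common words
word	syllables
a	1
the	1
and	1
blood	1
skin	1
head	1
arm	1
leg	1
back	1
eye	1
ear	1
hand	1
foot	1
feet	1
face	1
hair	1
chest	1
neck	1
throat	1
pain	1
ache	1
test	1
drug	1
pill	1
dose	1
flu	1
care	1
help	1
ask	1
tell	1
need	1
know	1
day	1
week	1
month	1
year	1
sick	1
bad	1
good	1
health	1
nurse	1
heart	1
lung	1
bone	1
vein	1
nerve	1
wound	1
pulse	1
sleep	1
food	1
salt	1
weight	1
gain	1
loss	1
stage	1
sign	1
cure	1
cell	1
scan	1
shot	1
clot	1
rash	1
cyst	1
stone	1
graft	1
swell	1
bruise	1
cramp	1
strain	1
sprain	1
cough	1
cold	1
sore	1
numb	1
weak	1
tired	2
rest	1
walk	1
run	1
eat	1
drink	1
go	1
do	1
get	1
feel	1
hurt	1
heal	1
treat	1
nerves	1
kidney	2
kidneys	2
doctor	2
doctors	2
body	2
pressure	2
treatment	2
symptom	2
symptoms	2
chronic	2
stable	2
fever	2
cancer	2
patient	2
stomach	2
muscle	2
liver	2
bladder	2
organ	2
tissue	2
damage	2
function	2
failure	2
transplant	2
surgeon	2
illness	2
sickness	2
disease	2
dosage	2
tablet	2
protein	2
answer	2
question	2
questions	2
water	2
swelling	2
dizzy	2
anxious	2
worried	2
nervous	2
healthy	2
stages	2
level	2
levels	2
urine	2
thirsty	2
insulin	3
infection	3
infections	3
hospital	3
medical	3
medicine	3
condition	3
diagnose	3
diagnosed	3
prevention	3
nutrition	3
dietitian	4
exercise	3
therapy	3
family	3
history	3
unstable	3
recovery	4
surgery	3
surgeries	3
vitamin	3
vitamins	3
sodium	3
potassium	4
calcium	3
disorder	3
transplanted	3
dialysis	4
diabetes	4
diabetic	4
medication	4
medications	4
hypertension	4
nephrology	4
nephrologist	4
urinalysis	5
laboratory	5
preventative	4
hereditary	5
deteriorate	5
anemia	4
creatinine	4
biopsy	3
ultrasound	3
appointment	3
emergency	4
specialist	3
referral	3
nutritionist	4
prescription	3
antibiotic	5
inflammation	4
transplantation	4
complication	4
complications	4
hemodialysis	6
abnormal	3
abnormality	5
evaluation	5
examination	5
rehabilitation	6
osteoporosis	6
cardiovascular	6
glomerular	4
filtration	3
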