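molecule,drug_class,drug_group,strengths
sertraline,SSRI,antidepressant,50;100
escitalopram,SSRI,antidepressant,10;20
citalopram,SSRI,antidepressant,10;20;40
fluoxetine,SSRI,antidepressant,20;40
paroxetine,SSRI,antidepressant,20;30
fluvoxamine,SSRI,antidepressant,50;100
venlafaxine,SNRI,antidepressant,37.5;75;150
desvenlafaxine,SNRI,antidepressant,50;100
duloxetine,SNRI,antidepressant,30;60
amitriptyline,TCA,antidepressant,10;25;50
clomipramine,TCA,antidepressant,25;75
dothiepin,TCA,antidepressant,25;75
doxepin,TCA,antidepressant,10;25;50
imipramine,TCA,antidepressant,10;25
nortriptyline,TCA,antidepressant,10;25
mirtazapine,NaSSA,antidepressant,15;30;45
phenelzine,MAOI,antidepressant,15
tranylcypromine,MAOI,antidepressant,10
moclobemide,RIMA,antidepressant,150;300
reboxetine,NRI,antidepressant,4
mianserin,TeCA,antidepressant,10;20
bupropion,NDRI,antidepressant,150
agomelatine,melatonin_agonist,antidepressant,25
vortioxetine,serotonin_modulator,antidepressant,5;10;20
quetiapine,antipsychotic,antipsychotic,25;100;200
olanzapine,antipsychotic,antipsychotic,2.5;5;10
risperidone,antipsychotic,antipsychotic,0.5;1;2
aripiprazole,antipsychotic,antipsychotic,10;15
lurasidone,antipsychotic,antipsychotic,40;80
lithium,mood_stabiliser,mood_stabiliser,250;450
carbamazepine,mood_stabiliser,mood_stabiliser,100;200;400
oxcarbazepine,mood_stabiliser,mood_stabiliser,150;300;600
sodium_valproate,mood_stabiliser,mood_stabiliser,100;200;500
lamotrigine,mood_stabiliser,mood_stabiliser,25;50;100;200
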