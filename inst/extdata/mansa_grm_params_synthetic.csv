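# scorewalk grm_parameters v1
# loglik=NA iterations=NA converged=NA
item,a,b1,b2,b3,b4,b5,b6
item01,1.38985,-3.74827505566,-2.89925366568,-1.931789584,-0.786646774229,0.664230074739,2.81914350183
item02,1.326675,-3.65703584373,-3.03779444009,-2.32527074202,-1.46578361447,-0.327151553215,1.69512004333
item03,1.200325,-3.53064612266,-2.8483966497,-2.06316153386,-1.1165903141,0.132202045506,2.2813045792
item04,1.2635,-3.63980889319,-2.90245121301,-2.05891902084,-1.05320095071,0.241467595764,2.26869387388
item05,1.453025,-3.75711307751,-2.95207830942,-2.03147875594,-0.934860306712,0.473539334194,2.6589449132
item06,1.38985,-3.84271434149,-3.22912521981,-2.5237140496,-1.67359469597,-0.54803116519,1.46244099619
item07,1.073975,-5.72712450284,-4.96625787938,-4.09027529199,-3.02865191255,-1.59267382528,1.56942629765
item08,1.38985,-3.79316770676,-3.10065095523,-2.31677282255,-1.3983897743,-0.255950366244,1.36484859982
item09,1.0108,-3.28938291652,-2.3224101196,-1.25870661537,-0.0672910161399,1.3024247607,2.94289838233
item10,1.326675,-3.5953905424,-2.82075806579,-1.93615065896,-0.885006585565,0.457839216088,2.50499995651
item11,1.2635,-3.68822331997,-2.90522410405,-2.00864204667,-0.938188475629,0.443185483865,2.62050754377
item12,1.13715,-3.60755096581,-2.77981712006,-1.84283318967,-0.746054549852,0.613421768076,2.51500494065
group:population,0,1
group:clinical,-1.15,1.5
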