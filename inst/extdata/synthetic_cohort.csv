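animal_id,group_id,day,width_mm,length_mm,alive
LN-TCV+L_a01,LN-TCV+L,0,4.52944253107387,5.66180316384234,1
LN-TCV+L_a01,LN-TCV+L,2,5.00619389850739,6.25774237313424,1
LN-TCV+L_a01,LN-TCV+L,4,4.91977833158567,6.14972291448209,1
LN-TCV+L_a01,LN-TCV+L,6,4.84404895148509,6.05506118935637,1
LN-TCV+L_a01,LN-TCV+L,8,4.80719932366702,6.00899915458378,1
LN-TCV+L_a01,LN-TCV+L,10,4.96295590016194,6.20369487520243,1
LN-TCV+L_a01,LN-TCV+L,12,4.9936290150626,6.24203626882824,1
LN-TCV+L_a01,LN-TCV+L,14,5.32153844269126,6.65192305336407,1
LN-TCV+L_a01,LN-TCV+L,16,5.52756336959373,6.90945421199216,1
LN-TCV+L_a01,LN-TCV+L,18,5.99052525242973,7.48815656553716,1
LN-TCV+L_a01,LN-TCV+L,20,6.4383933318795,8.04799166484938,1
LN-TCV+L_a02,LN-TCV+L,0,4.59097335801891,5.73871669752364,1
LN-TCV+L_a02,LN-TCV+L,2,5.02715847876906,6.28394809846132,1
LN-TCV+L_a02,LN-TCV+L,4,4.79091969401204,5.98864961751505,1
LN-TCV+L_a02,LN-TCV+L,6,4.82574260818684,6.03217826023355,1
LN-TCV+L_a02,LN-TCV+L,8,4.75337920596773,5.94172400745966,1
LN-TCV+L_a02,LN-TCV+L,10,4.84360329365587,6.05450411706984,1
LN-TCV+L_a02,LN-TCV+L,12,5.02156862986618,6.27696078733273,1
LN-TCV+L_a02,LN-TCV+L,14,5.30911718212444,6.63639647765555,1
LN-TCV+L_a02,LN-TCV+L,16,5.61979018321331,7.02473772901663,1
LN-TCV+L_a02,LN-TCV+L,18,6.04539206071184,7.5567400758898,1
LN-TCV+L_a02,LN-TCV+L,20,6.18188632124473,7.72735790155591,1
LN-TCV+L_a03,LN-TCV+L,0,4.51368909188514,5.64211136485642,1
LN-TCV+L_a03,LN-TCV+L,2,5.0135665332333,6.26695816654163,1
LN-TCV+L_a03,LN-TCV+L,4,5.06496976633409,6.33121220791762,1
LN-TCV+L_a03,LN-TCV+L,6,4.85194271200309,6.06492839000387,1
LN-TCV+L_a03,LN-TCV+L,8,4.74549478143869,5.93186847679837,1
LN-TCV+L_a03,LN-TCV+L,10,4.88333381861386,6.10416727326732,1
LN-TCV+L_a03,LN-TCV+L,12,5.11947868050874,6.39934835063593,1
LN-TCV+L_a03,LN-TCV+L,14,5.2001191549218,6.50014894365225,1
LN-TCV+L_a03,LN-TCV+L,16,5.57476031145102,6.96845038931378,1
LN-TCV+L_a03,LN-TCV+L,18,5.81356359000841,7.26695448751051,1
LN-TCV+L_a03,LN-TCV+L,20,6.25740478262766,7.82175597828457,1
LN-TCV+L_a04,LN-TCV+L,0,4.70019815648664,5.8752476956083,1
LN-TCV+L_a04,LN-TCV+L,2,4.94051980248012,6.17564975310015,1
LN-TCV+L_a04,LN-TCV+L,4,4.96723126849869,6.20903908562336,1
LN-TCV+L_a04,LN-TCV+L,6,4.84089646156445,6.05112057695556,1
LN-TCV+L_a04,LN-TCV+L,8,4.64268764274851,5.80335955343563,1
LN-TCV+L_a04,LN-TCV+L,10,4.8475566498202,6.05944581227525,1
LN-TCV+L_a04,LN-TCV+L,12,5.09083547400439,6.36354434250549,1
LN-TCV+L_a04,LN-TCV+L,14,5.19849629795347,6.49812037244184,1
LN-TCV+L_a04,LN-TCV+L,16,5.48174945186022,6.85218681482528,1
LN-TCV+L_a04,LN-TCV+L,18,5.74838469777244,7.18548087221555,1
LN-TCV+L_a04,LN-TCV+L,20,6.18881393245348,7.73601741556685,1
LN-TCV+L_a05,LN-TCV+L,0,4.60214094902757,5.75267618628446,1
LN-TCV+L_a05,LN-TCV+L,2,5.09234180761066,6.36542725951333,1
LN-TCV+L_a05,LN-TCV+L,4,4.96960993340342,6.21201241675428,1
LN-TCV+L_a05,LN-TCV+L,6,4.78417898016334,5.98022372520418,1
LN-TCV+L_a05,LN-TCV+L,8,4.72008344475733,5.90010430594667,1
LN-TCV+L_a05,LN-TCV+L,10,4.74188301702291,5.92735377127864,1
LN-TCV+L_a05,LN-TCV+L,12,5.0127764944274,6.26597061803425,1
LN-TCV+L_a05,LN-TCV+L,14,5.29215857005212,6.61519821256515,1
LN-TCV+L_a05,LN-TCV+L,16,5.56947138757517,6.96183923446896,1
LN-TCV+L_a05,LN-TCV+L,18,5.90500133575956,7.38125166969945,1
LN-TCV+L_a05,LN-TCV+L,20,6.10981742788401,7.63727178485502,1
LN-TCV+L_a06,LN-TCV+L,0,4.5148289999171,5.64353624989638,1
LN-TCV+L_a06,LN-TCV+L,2,4.99806336477609,6.24757920597012,1
LN-TCV+L_a06,LN-TCV+L,4,5.04971500619063,6.31214375773829,1
LN-TCV+L_a06,LN-TCV+L,6,4.62250740829235,5.77813426036543,1
LN-TCV+L_a06,LN-TCV+L,8,4.79106160834733,5.98882701043416,1
LN-TCV+L_a06,LN-TCV+L,10,4.81848096735914,6.02310120919892,1
LN-TCV+L_a06,LN-TCV+L,12,5.00536452112487,6.25670565140609,1
LN-TCV+L_a06,LN-TCV+L,14,5.32788593182037,6.65985741477546,1
LN-TCV+L_a06,LN-TCV+L,16,5.43471671201899,6.79339589002374,1
LN-TCV+L_a06,LN-TCV+L,18,5.83608835468418,7.29511044335523,1
LN-TCV+L_a06,LN-TCV+L,20,6.2054107998635,7.75676349982938,1
PBS_a01,PBS,0,4.50908389284228,5.63635486605285,1
PBS_a01,PBS,2,5.02461613203082,6.28077016503852,1
PBS_a01,PBS,4,5.32702374258418,6.65877967823022,1
PBS_a01,PBS,6,5.86210469745653,7.32763087182066,1
PBS_a01,PBS,8,6.17071993233864,7.7133999154233,1
PBS_a01,PBS,10,6.6603378969736,8.325422371217,1
PBS_a01,PBS,12,6.79038946341894,8.48798682927367,1
PBS_a01,PBS,14,7.29445394703453,9.11806743379316,1
PBS_a01,PBS,16,7.78058543250584,9.7257317906323,1
PBS_a01,PBS,18,8.06630921956632,10.0828865244579,1
PBS_a01,PBS,20,8.35505855451333,10.4438231931417,1
PBS_a02,PBS,0,4.5910655692402,5.73883196155025,1
PBS_a02,PBS,2,4.94592846044905,6.18241057556131,1
PBS_a02,PBS,4,5.26992705793888,6.5874088224236,1
PBS_a02,PBS,6,5.805691229412,7.257114036765,1
PBS_a02,PBS,8,5.92331939196743,7.40414923995929,1
PBS_a02,PBS,10,6.61390962781216,8.26738703476521,1
PBS_a02,PBS,12,6.88415908770303,8.60519885962878,1
PBS_a02,PBS,14,7.63574092510481,9.54467615638101,1
PBS_a02,PBS,16,7.65020184954621,9.56275231193276,1
PBS_a02,PBS,18,7.94386943605777,9.92983679507221,1
PBS_a02,PBS,20,8.90386557390544,11.1298319673818,1
PBS_a03,PBS,0,4.6996160863035,5.87452010787938,1
PBS_a03,PBS,2,5.13259356891826,6.41574196114782,1
PBS_a03,PBS,4,5.52353911416845,6.90442389271056,1
PBS_a03,PBS,6,5.96831114535576,7.46038893169469,1
PBS_a03,PBS,8,6.21945485768201,7.77431857210252,1
PBS_a03,PBS,10,6.69785375292854,8.37231719116067,1
PBS_a03,PBS,12,6.92366179234956,8.65457724043695,1
PBS_a03,PBS,14,7.47453874619679,9.34317343274599,1
PBS_a03,PBS,16,7.69627382896361,9.62034228620451,1
PBS_a03,PBS,18,8.16425260976762,10.2053157622095,1
PBS_a03,PBS,20,8.50743806299169,10.6342975787396,1
PBS_a04,PBS,0,4.49158396051417,5.61447995064272,1
PBS_a04,PBS,2,4.9542485695708,6.1928107119635,1
PBS_a04,PBS,4,5.15950036084648,6.4493754510581,1
PBS_a04,PBS,6,5.6499826762122,7.06247834526525,1
PBS_a04,PBS,8,6.10920615072855,7.63650768841068,1
PBS_a04,PBS,10,6.54780092077405,8.18475115096756,1
PBS_a04,PBS,12,6.95979969786178,8.69974962232723,1
PBS_a04,PBS,14,7.64686136396371,9.55857670495463,1
PBS_a04,PBS,16,8.07777034118015,10.0972129264752,1
PBS_a04,PBS,18,8.33724354543477,10.4215544317935,1
PBS_a04,PBS,20,8.63036707398233,10.7879588424779,1
PBS_a05,PBS,0,4.57083799134748,5.71354748918435,1
PBS_a05,PBS,2,5.00037885049067,6.25047356311334,1
PBS_a05,PBS,4,5.44102679654041,6.80128349567551,1
PBS_a05,PBS,6,5.91869623452351,7.39837029315439,1
PBS_a05,PBS,8,6.25216882644931,7.81521103306163,1
PBS_a05,PBS,10,6.49430574388358,8.11788217985447,1
PBS_a05,PBS,12,6.94392766079395,8.67990957599243,1
PBS_a05,PBS,14,7.35989576513709,9.19986970642137,1
PBS_a05,PBS,16,7.73174120484376,9.6646765060547,1
PBS_a05,PBS,18,8.36553250118791,10.4569156264849,1
PBS_a05,PBS,20,8.68054734840401,10.850684185505,1
PBS_a06,PBS,0,4.58705808127197,5.73382260158997,1
PBS_a06,PBS,2,5.04758298553192,6.3094787319149,1
PBS_a06,PBS,4,5.3651800125356,6.7064750156695,1
PBS_a06,PBS,6,5.95479009865501,7.44348762331876,1
PBS_a06,PBS,8,6.20005110302891,7.75006387878613,1
PBS_a06,PBS,10,6.51391581750485,8.14239477188107,1
PBS_a06,PBS,12,6.7640737443995,8.45509218049938,1
PBS_a06,PBS,14,7.3862551603254,9.23281895040675,1
PBS_a06,PBS,16,7.97209787788924,9.96512234736155,1
PBS_a06,PBS,18,8.44004467501954,10.5500558437744,1
PBS_a06,PBS,20,8.49089616198069,10.6136202024759,1
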