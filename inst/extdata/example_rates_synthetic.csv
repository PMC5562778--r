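"concentration_uM","rate_mean","rate_sem","pathway","protein_source"
25,0.0267819664243344,0.000573891320369912,"AP","microsomes"
50,0.0446544378208732,0.00352840955426569,"AP","microsomes"
100,0.0683585513874752,0.0027101604685064,"AP","microsomes"
250,0.104874514278013,0.0118497117767644,"AP","microsomes"
500,0.13158105476706,0.0103946218002561,"AP","microsomes"
1000,0.121543471568724,0.00533623172549181,"AP","microsomes"
25,0.0580332809693735,0.00288287756743682,"EE","microsomes"
50,0.0967111131097204,0.00216301057106658,"EE","microsomes"
100,0.140462343587572,0.00740420501953207,"EE","microsomes"
250,0.248373329244266,0.00738521930889085,"EE","microsomes"
500,0.326198774742613,0.0260727767268349,"EE","microsomes"
1000,0.324940912782037,0.0125726882763025,"EE","microsomes"
25,0.12246712373719,0.00591829908184449,"HE","microsomes"
50,0.18107776006822,0.0123670648788963,"HE","microsomes"
100,0.249236411739041,0.0150418936248693,"HE","microsomes"
250,0.280457141693503,0.00483732836602257,"HE","microsomes"
500,0.296823398246856,0.0106103673164788,"HE","microsomes"
1000,0.330658062933145,0.00540045227798936,"HE","microsomes"
25,0.0154979590546742,0.00114753298067123,"HA","microsomes"
50,0.0325973365758808,0.00101124174782871,"HA","microsomes"
100,0.0596572482801057,0.00429515280849011,"HA","microsomes"
250,0.116428130155157,0.00711920350834405,"HA","microsomes"
500,0.179491587392153,0.00542501118967814,"HA","microsomes"
1000,0.236420342790612,0.0180647893468841,"HA","microsomes"
25,0.00734907489017331,0.000602083863257133,"M5","microsomes"
50,0.0129781635614768,0.0010206976774406,"M5","microsomes"
100,0.0250903891073588,0.000333316211062652,"M5","microsomes"
250,0.0499825989128811,0.0032037511466588,"M5","microsomes"
500,0.0780999318156409,0.002550889633192,"M5","microsomes"
1000,0.112057253594542,0.00754912236799555,"M5","microsomes"
25,0.00884400665450272,0.000269990549789743,"HEG","microsomes"
50,0.0155573948115151,0.00153524958478731,"HEG","microsomes"
100,0.0369327975095086,0.00306177663725137,"HEG","microsomes"
250,0.0914685614262782,0.00485756887046677,"HEG","microsomes"
500,0.16474152811747,0.00438214605373702,"HEG","microsomes"
1000,0.309545317481631,0.0149028990973755,"HEG","microsomes"
2000,0.474098922168524,0.0626226108032287,"HEG","microsomes"
4000,0.75755541748681,0.0351026202356628,"HEG","microsomes"
8000,1.07987903752229,0.0418514354949237,"HEG","microsomes"
25,0.109338554225707,0.00527501846787675,"OE","S9"
50,0.194883343872996,0.00568420808189015,"OE","S9"
100,0.342726099323964,0.0210686644080338,"OE","S9"
250,0.637858685251828,0.0105816160805008,"OE","S9"
500,1.08357980129519,0.034308176211212,"OE","S9"
1000,1.42949094696599,0.110118887357518,"OE","S9"
2000,1.58655929857372,0.142481872774922,"OE","S9"
4000,1.8472616766792,0.204245515770146,"OE","S9"
8000,1.65757854117823,0.0949894747909884,"OE","S9"
25,4.53327116577372e-05,3.03641762800183e-06,"HES","S9"
50,9.13580830930836e-05,3.09162649899802e-06,"HES","S9"
100,0.000177720201244459,4.62284751575021e-06,"HES","S9"
250,0.0003638247160976,1.32195520714563e-05,"HES","S9"
500,0.000525258974131874,3.63153133414781e-05,"HES","S9"
1000,0.000852786624815286,5.68047174249935e-05,"HES","S9"
2000,0.00105880176346223,2.92243302371009e-05,"HES","S9"
4000,0.00126936147115196,0.000121871863469639,"HES","S9"
8000,0.00131258718676778,6.56328444005512e-05,"HES","S9"
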