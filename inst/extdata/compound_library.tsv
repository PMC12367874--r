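compound	formula	monoisotopic_mass	rt_seconds	function_group
creatine	C4H9N3O2	131.06947654223	NA	energy metabolism
phosphocreatine	C4H10N3O5P	211.0358070631	NA	energy metabolism
AMP	C10H14N5O7P	347.06308444018	NA	purine metabolism
ADP	C10H15N5O10P2	427.02941496105	NA	purine metabolism
ATP	C10H16N5O13P3	506.99574548192	NA	purine metabolism
cyclic AMP	C10H12N5O6P	329.05251975644	NA	purine metabolism
GMP	C10H14N5O8P	363.05799905978	NA	purine metabolism
cyclic GMP	C10H12N5O7P	345.04743437604	NA	purine metabolism
adenosine	C10H13N5O4	267.09675391931	NA	purine metabolism
deoxyadenosine	C10H13N5O3	251.10183929971	NA	purine metabolism
deoxyguanosine	C10H13N5O4	267.09675391931	NA	purine metabolism
inosine	C10H12N4O5	268.08076950204	NA	purine metabolism
xanthine	C5H4N4O2	152.03342538668	NA	purine metabolism
hypoxanthine	C5H4N4O	136.03851076708	NA	purine metabolism
L-glutamine	C5H10N2O3	146.0691421891	NA	amino acid
pantothenic acid	C9H17NO5	219.11067264799	NA	energy metabolism
glutathione (reduced)	C10H17N3O6S	307.08380627719	NA	oxidative stress
glutathione (oxidised)	C20H32N6O12S2	612.15196249024	NA	oxidative stress
lactic acid	C3H6O3	90.03169405122	NA	extracellular marker
thymidine	C10H14N2O5	242.09027155658	NA	extracellular marker
deoxycytidine	C9H13N3O4	227.09060590971	NA	extracellular marker
L-alanine	C3H7NO2	89.04767846849	NA	extracellular marker
N-acetylaspartic acid	C6H9NO5	175.04807239143	NA	extracellular marker
cytosine	C4H5N3O	111.04326179435	NA	extracellular marker
sn-glycero-3-phosphoethanolamine	C5H14NO6P	215.05587380138	NA	glycerophospholipid metabolism
taurine	C2H7NO3S	125.01466408809	NA	amino acid
carnitine	C7H15NO3	161.10519334465	NA	amino acid
glucose	C6H12O6	180.06338810244	NA	energy metabolism
L-glutamic acid	C5H9NO4	147.05315777183	NA	energy metabolism
creatinine	C4H7N3O	113.05891185849	NA	energy metabolism
nicotinamide	C6H6N2O	122.04801282162	NA	energy metabolism
succinic acid	C4H6O4	118.02660867082	NA	energy metabolism
citric acid	C6H8O7	192.02700259376	NA	energy metabolism
fumaric acid	C4H4O4	116.01095860668	NA	energy metabolism
malic acid	C4H6O5	134.02152329042	NA	energy metabolism
pyruvic acid	C3H4O3	88.01604398708	NA	energy metabolism
uridine	C9H12N2O6	244.06953611204	NA	purine metabolism
cytidine	C9H13N3O5	243.08552052931	NA	purine metabolism
guanosine	C10H13N5O5	283.09166853891	NA	purine metabolism
uric acid	C5H4N4O3	168.02834000628	NA	purine metabolism
Cer 32:1;O2	C32H63NO3	509.48079488401	NA	ceramide signalling
Cer 33:1;O2	C33H65NO3	523.49644494815	NA	ceramide signalling
Cer 34:0;O2	C34H69NO3	539.52774507643	NA	ceramide signalling
Cer 34:1;O2	C34H67NO3	537.51209501229	NA	ceramide signalling
Cer 34:2;O2	C34H65NO3	535.49644494815	NA	ceramide signalling
Cer 35:1;O2	C35H69NO3	551.52774507643	NA	ceramide signalling
Cer 36:1;O2	C36H71NO3	565.54339514057	NA	ceramide signalling
Cer 36:2;O2	C36H69NO3	563.52774507643	NA	ceramide signalling
Cer 37:1;O2	C37H73NO3	579.55904520471	NA	ceramide signalling
Cer 38:1;O2	C38H75NO3	593.57469526885	NA	ceramide signalling
Cer 38:2;O2	C38H73NO3	591.55904520471	NA	ceramide signalling
Cer 39:1;O2	C39H77NO3	607.59034533299	NA	ceramide signalling
Cer 40:1;O2	C40H79NO3	621.60599539713	NA	ceramide signalling
Cer 40:2;O2	C40H77NO3	619.59034533299	NA	ceramide signalling
Cer 41:1;O2	C41H81NO3	635.62164546127	NA	ceramide signalling
Cer 41:1;O3	C41H81NO4	651.61656008087	NA	ceramide signalling
Cer 41:2;O2	C41H79NO3	633.60599539713	NA	ceramide signalling
Cer 41:3;O2	C41H77NO3	631.59034533299	NA	ceramide signalling
Cer 42:1;O2	C42H83NO3	649.63729552541	NA	ceramide signalling
Cer 42:1;O3	C42H83NO4	665.63221014501	NA	ceramide signalling
Cer 42:2;O2	C42H81NO3	647.62164546127	NA	ceramide signalling
Cer 42:2;O3	C42H81NO4	663.61656008087	NA	ceramide signalling
Cer 42:3;O2	C42H79NO3	645.60599539713	NA	ceramide signalling
Cer 42:4;O2	C42H77NO3	643.59034533299	NA	ceramide signalling
Cer 43:2;O2	C43H83NO3	661.63729552541	NA	ceramide signalling
Cer 43:3;O2	C43H81NO3	659.62164546127	NA	ceramide signalling
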