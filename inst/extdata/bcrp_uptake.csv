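compound,role,raw_482R,pct_482R,raw_482G,pct_482G,raw_482T,pct_482T
Mitoxantrone,training,23.71,100,27.43,100,25.92,100
Caffeine,training,29.64,125,41.42,151,46.28,140
Ciprofloxacin,training,57.38,242,63.91,233,45.88,177
Cyclosporin,training,70.18,296,66.93,244,63.76,246
Diltiazem,training,55.95,236,59.52,217,32.40,125
Erythromycin,training,37.93,160,48.00,175,50.02,193
Estradiol,training,29.87,126,31.27,114,26.70,103
Febendazole,training,30.82,130,34.83,127,38.36,148
Ketoconazole,training,64.50,272,70.22,256,68.17,263
Nifedipine,training,38.17,161,42.52,155,38.36,148
Novobiocin,training,56.90,240,77.35,282,71.02,274
Quinidine,training,38.64,163,41.97,153,33.17,128
Raloxifene,training,46.47,196,55.95,204,23.58,91
Rhodamine 123,training,44.57,188,33.74,123,43.02,166
Riboflavin,training,41.25,174,35.92,131,36.80,142
Saquinavir,training,46.00,194,57.33,209,72.83,281
Tamoxifene,training,31.30,132,38.67,141,40.95,158
Verapamil,training,29.87,126,58.42,213,31.36,121
Acyclovir,test,50.26,212,66.91,244,68.95,266
Epinephrine,test,42.91,181,33.73,123,24.89,115
Foscarnet,test,29.87,126,30.45,111,33.17,128
FumitremorginC,test,26.76,305,79.82,291,84.75,327
Ketoconazole,test,64.02,270,70.77,258,68.17,263
PEITC,test,68.28,288,85.85,313,85.27,329
Quercetin,test,58.56,247,69.12,252,61.95,239
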