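"sample_id","f1","f2","f3","f4","status"
"c1_s001_r1","0.92872471613405239","0.92814519259895567","0.82729168642552364","0.79975134447553042",1
"c1_s002_r1","0.580322831777765","0.7324020540138515","0.71841927712357667","0.58948699411867367",1
"c1_s003_r1","0.63057074895645404","0.88960670668099306","0.7752279895740033","0.68577121692254139",1
"c1_s004_r1","0.65877070488631972","0.74676805113216971","0.75917450524627261","0.73149949048879126",1
"c1_s005_r1","0.60293266588805161","0.61061992769145557","0.60169474042289783","0.82185505345073473",1
"c1_s006_r1","0.60527200547718918","0.66926717004628045","0.67239360448879937","0.63006829213144855",1
"c1_s007_r1","0.77481393402905507","0.69951775777324288","0.61291489774314079","0.67145672484712737",1
"c1_s008_r1","0.68830447741128475","0.79881641494999445","0.77187105530842448","0.56884473273906133",1
"c1_s009_r1","0.71526576262822328","0.78397503596240714","0.71106528777693356","0.66089875685507415",1
"c1_s010_r1","0.91899781073293796","0.77053418309055","0.69215332320282952","0.65984733869050272",1
"c1_s011_r1","0.73569862303290223","0.83059647208116871","0.65795095406580018","0.83505175809229537",1
"c1_s012_r1","0.97167517831307237","0.5612003783407149","0.64378741237147341","0.75911900270892207",1
"c2_s001_r1","0.31005254556285688","0.30763714738605741","0.2384415793369081","0.2207295437211072",2
"c2_s002_r1","0.39310719955200968","0.31591552782627275","0.21333403117486252","0.26882981347048274",2
"c2_s003_r1","0.27372576514334673","0.35436741847096986","0.1360482912818862","0.26539314082191401",2
"c2_s004_r1","0.29923318952873357","0.37048073526130471","0.16741607561565899","0.26953924117546757",2
"c2_s005_r1","0.33671530065456345","0.331896914255711","0.21109632723620297","0.12141065125554823",2
"c2_s006_r1","0.47071625451376065","0.41092497889710555","0.24423976696978866","0.35872746718579701",2
"c2_s007_r1","0.372374026252838","0.37691541946571122","0.29375976911616519","0.46357944344465907",2
"c2_s008_r1","0.34810360487079173","0.41534736747789358","0.54226929771594268","0.23545765263656032",2
"c2_s009_r1","0.14321317557747484","0.42606835026809375","0.33425853501472991","0.361899216878734",2
"c2_s010_r1","0.33182502834808281","0.37006235065723242","0.300424823625213","0.32363935984013215",2
"c2_s011_r1","0.31659914506773501","0.34326271608459547","0.30292198420016503","0.38465008987516436",2
"c2_s012_r1","0.21000923703718283","0.20773982817430792","0.26065765708786975","0.24263542611503069",2
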