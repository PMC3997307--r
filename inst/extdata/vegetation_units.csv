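site_id,center_lat,center_lon,vegetation_unit,rainfall_regime,migratory,apcv,mat,mafd,reported_bin
1,?,?,Arid woodland,summer,FALSE,?,?,?,?
2,?,?,Central-western Plains,irregular,FALSE,100,17.0,0,+
3,?,?,Dwaalboom Thornveld,summer,FALSE,29,19.4,19,+-
4,?,?,Egoli Granite,summer,TRUE,26,16.0,29,+-
5,?,?,Carletonville Dolomite,summer,TRUE,28,16.1,37,+
6,?,?,Rand Highveld,summer,TRUE,27,15.8,28,+-
7,?,?,Soweto Highveld,summer,TRUE,27,14.8,41,+
8,?,?,Wakkerstroom Montane,summer,TRUE,22,14.1,31,+-
9,?,?,KZN Highland Thornveld,summer,TRUE,25,16.5,15,-
10,?,?,Northern KZN Moist,summer,TRUE,23,16.2,20,-
11,?,?,Eastern Free State Sandy,summer,TRUE,26,13.6,51,+
12,?,?,Winburg Grassy Shrubland,summer,TRUE,31,15.3,41,+
13,?,?,Ngongoni Veld,summer,TRUE,22,17.7,2,-
14,?,?,Swartland Shale,winter,TRUE,32,17.2,3,-
15,?,?,Swartland Alluvium,winter,TRUE,27,17.1,3,-
16,?,?,Swartland Granite,winter,TRUE,30,16.3,3,-
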