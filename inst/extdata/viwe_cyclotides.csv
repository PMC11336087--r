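name,sequence,printed_mw,complete
viul D,GIPCGESCVWIPCLTSAIGCSCKSKVCYKN,3124.32,TRUE
viul M,GIPCGESCVFIPCLTAAIGCSCKSKVCYRN,3097.32,TRUE
vitri A,GIPCGESCVWIPCITSAIGCSCKSKVCYRN,3152.33,TRUE
vitri 98,GIPCGETCVFSGCYSVTFGCACEKRVCYKN,3199.26,TRUE
Part of vitri 60 precursor,GIPCGETCIFGRCHTGIIGCACEKYMCCKN,3185.24,TRUE
vitri 42a,GTIFNCGESCFQGTCYTKGCACGDWKLCYGEN,3433.25,TRUE
vitri 28 (incomplete)*,VPSSDCLETCFGGKCNAHRCTCSQWPLCAKN,3333.32,FALSE
vinc A (incomplete)*,PVCGETCTLGTCYTAGCSCSWPVCTRN,2787.01,FALSE
varv peptide F,GVPICGETCTLGTCYTAGCSCSWPVCTRN,2957.12,TRUE
varv peptide D,GLPICGETCVGGSCNTPGCSCSWPVCTRN,2876.07,TRUE
Kalata S,GLPVCGETCVGGTCNTPGCSCSWPVCTRN,2876.07,TRUE
Kalata B1 (incomplete)*,LPVCGETCVGGTCNTPGCTCSWPVCTRN,2833.07,FALSE
CyO8,GTLPCGESCVWIPCISSVVGCSCKSKVCYKN,3225.37,TRUE
CyO4,GIPCGESCVWIPCISSAIGCSCKNKVCYRN,3165.33,TRUE
CyO3,GIPCGESCVWIPCLTSAIGCSCKSKVCYRN,3152.33,TRUE
CyO12,GLPICGETCVGGTCNTPGCSCSWPVCTRN,2890.09,TRUE
viwe 1,GLPVCGETCVGGPCNTPGCSCSRPVCTRN,2842.10,TRUE
viwe 2,GLPICGETCVGGTCNTPGCICSWPVCTTN,2861.09,TRUE
viwe 3,GIPICGETCVGGTCNTPGCSCSWPVCVRN,2888.11,TRUE
viwe 4,GIPICGETCVGGTCNTPGCSCSWPVCTRN,2890.09,TRUE
viwe 5,GLPVCGETCVGGTCNTLGCSCSWPVCTRN,2892.11,TRUE
viwe 6,GMPVCGETCVGGTCNTPGCSCSWPVCTRN,2894.03,TRUE
viwe 7,GLPVCGETCVGGTCNTPGCSCSWPVCKRN,2903.12,TRUE
viwe 8,GLPICGETCVGGSCNTPGCSCSWPMCVRN,2906.07,TRUE
viwe 9,GLPVCGETCVGGTCNTPGCSCSWPVCMRN,2906.07,TRUE
viwe 10,GLPICGETCVGGTCNTPGCSCSWPVCMRN,2920.08,TRUE
viwe 11,GIPICGETCTLGTCYTAGCSCSWPVCTRN,2971.14,TRUE
viwe 12,GLPICGETCTLGTCYTAGCSCSWPVCTRN,2971.14,TRUE
viwe 13,GVPICGETCTLGTCYTAGCTCSWPVCTRN,2971.14,TRUE
viwe 14,GHCGESCMVLPCFTASRGCSCSGAICWKN,2982.11,TRUE
viwe 15,GVPICGDTCFGGTCYTPGCSCSWPVCMRN,2989.07,TRUE
viwe 16,SIPCGESCVFIPCLTGAIGCACKSSVCYLN,3013.24,TRUE
viwe 17,GSAVPCGESCFFGGGCDTPGCSCTWPACTKN,3017.05,TRUE
viwe 18,SIPCAESCAFVPCYGIIPCSCKNGICYSN,3017.18,TRUE
viwe 19,GLPVCGETCLGGTCNTPGCSCSWPVCVKYD,3024.15,TRUE
viwe 20,GSIFNCGETCILGTCYTPGCSCVYGACSKN,3026.13,TRUE
viwe 21,GSIFNCGESCVLGTCYTSGCSCVYGLCSKN,3030.13,TRUE
viwe 22,GSIFNCGESCVLGTCYTPGCSCVYGLCSKN,3040.15,TRUE
viwe 23,GVACPETCIFTSCFITSCTCDHGRCRRN,3055.19,TRUE
viwe 24,GIPCGESCVFIPCLTAAIGCSCSSKVCYRN,3056.26,TRUE
viwe 25,GYPCVETCVFSGCFITNCICNYGSCVWN,3057.12,TRUE
viwe 26,GSVFNCGESCLGGKCNTPDCTCSFPLCTKN,3060.15,TRUE
viwe 27,GSVFNCGESCLGGTCNTPGCTCSSFPLCTKN,3062.13,TRUE
viwe 28,GIPCAETCAFIPCMATAVFGCSCSNNVCYN,3064.13,TRUE
viwe 29,GSIPCAESCAFVPCYGIIPCSCKNGICYSN,3074.20,TRUE
viwe 30,GWSCQETCIFSSCYLTGCTCSYSVCKKN,3076.15,TRUE
viwe 31,GIPCGESCVWIPCITAAIGCSCSSNVCYRN,3081.22,TRUE
viwe 32,GIPCGESCVFIPCITAAIGCSCSNKVCYRN,3083.27,TRUE
viwe 33,GIPCGESCVFIPCLTAAIGCSCSNKVCYRN,3083.27,TRUE
viwe 34,GSVFNCGETCIWGTCYTPGCSCVYGACSKN,3085.11,TRUE
viwe 35,GIPCGESCVCITCISSAIGCSCKIKVCYRN,3085.28,TRUE
viwe 36,GIPCAESCVWIPCTITALLGCGCSNKVCYN,3093.28,TRUE
viwe 37,GVPTCDESCVLGTCFTPDCTCSWPICLRN,3095.19,TRUE
viwe 38,GIPCGESCVWIPCISSVIGCSCSSKVCYKN,3097.28,TRUE
viwe 39,GQFCGESCIVSSCYITRCTCTANFCYRN,3104.16,TRUE
viwe 40,GIPCGESCVWIPCISSVVGCSCSSKVCYRN,3111.27,TRUE
viwe 41,GLYVCGERCLRGRCNAPGCICTNKICTKN,3120.36,TRUE
viwe 42,GRFCLETCVFSSCFITGCDCEFTSCFKN,3122.17,TRUE
viwe 43,GIPCGESCVWIPCITAAIGCSCSNKVCYRN,3122.28,TRUE
viwe 44,GIPCGESCVWIPCVTVVIGCSCSSNVCYRN,3123.27,TRUE
viwe 45,GIPCAESCVWIPCTITALLGCSCSNKVCYN,3123.29,TRUE
viwe 46,GSIFKCGETCVLGTCYTPGCHCIWGVCAKN,3125.26,TRUE
viwe 47,GVLPCGESCVFIPCVTAVIGCACKSSVCYKN,3125.34,TRUE
viwe 48,GSSCYESCYLIPCITSIAGCSCNQNTCTDD,3126.09,TRUE
viwe 49,GDVCTETCFTDYCFLGGCTCYWPVCKKN,3131.16,TRUE
viwe 50,GPLCGDTCVYDPCLISAPCKCKNKVCYRN,3138.31,TRUE
viwe 51,GSIFNCGETCLLGTCYTSGCSCVYRVCSKD,3144.20,TRUE
viwe 52,GIPCGETCLFGGCNTSIFGCACEKRVCYKN,3148.26,TRUE
viwe 53,GSIPCGESCVWIPCISGIAGCSCSNKVCYKN,3153.28,TRUE
viwe 54,GIPCGITCELNPCHSFVPCTCQHRVCYSN,3156.24,TRUE
viwe 55,GVPCGESCVFNPCLTGVVLCRCSSYVCFKD,3160.29,TRUE
viwe 56,GSVPCGESCVWIPCISAVVGCSCSNKVCYKN,3167.29,TRUE
viwe 57,GSTPCGESCVWIPCISAVVGCSCSNKVCYKN,3169.27,TRUE
viwe 58,GSTPCGESCVWIPCISSVVGCSCSNKVCYLN,3170.26,TRUE
viwe 59,GSTPCGESCVWIPCISAVVGCSCSNKVCYMN,3172.22,TRUE
viwe 60,GRVPCGETCSLGTCYFAGCTCDWPICWRN,3173.20,TRUE
viwe 61,GSTPCGESCVWIPCISSIVGCSCSSKVCYMN,3175.22,TRUE
viwe 62,GLTCVESCIVIPCVTGLLGCYCSNHICYKN,3180.35,TRUE
viwe 63,GSIPCGESCVWIPCISAVVGCSCSNKVCYKN,3181.31,TRUE
viwe 64,GIPCGESCVWIPCLTSTIGCSCKSKVCYRN,3182.34,TRUE
viwe 65,GVGAYCGESCVLIPCLSAIIGCSCSNSDCFKN,3188.27,TRUE
viwe 66,SIPCAESCVWIPCISSVVGCSCKSKVCYRN,3196.36,TRUE
viwe 67,GIPCGETCIFSGCYSVTFGCACEKRVCYKN,3213.28,TRUE
viwe 68,GVLPCGESCVWIPCISSVVGCSCKSKVCYKN,3223.39,TRUE
viwe 69,GFSCMESCILLPCATKYIGCSCENKLCVKN,3232.35,TRUE
viwe 70,GSSKCWETCVLIPCATAILGCSCKDFICVKN,3267.42,TRUE
viwe 71,GIPCGESCVWIQCISSAIGCYCNNKVCFWN,3272.29,TRUE
viwe 72,GLVSCGQSCYRTPCVALTTCSCRFHVCYKN,3274.35,TRUE
viwe 73,GTIFDCGESCLLGKCYTPGCACGSWGLCYGQN,3281.23,TRUE
viwe 74,GTIFDCGESCVFGTCYTPGCACGSWALCYGQN,3288.17,TRUE
viwe 75,GTFPCGESCVWIPCLSKVIGCACKSKVCYKN,3298.44,TRUE
viwe 76,GLNCGETCWGFSCDRDDCSCWTWPYCSKN,3311.12,TRUE
viwe 77,GTIFDCGESCLLGTCYTKGCSCGSWKLCYGTN,3345.28,TRUE
viwe 78,GWLHCGETCRITPCLAADLMCFCTDGVCLRN,3376.37,TRUE
viwe 79,GSQHCAETCYLIPCLTTQIGCSCINRACYRN,3396.39,TRUE
viwe 80,SLFNCGETCLWGTCYTPGCNCNKWRVCEKN,3404.32,TRUE
viwe 81,GWISCVEACYYLPCASRVFGCSCVRNVCMRN,3464.41,TRUE
viwe 82,GTIFNCGESCFHGKCYTKGCACGDWKLCYGEN,3469.30,TRUE
viwe 83,GEHCYEVCYFNPCVTRLLGCYCHLHMCIKN,3523.41,TRUE
viwe 84,GQARFCHETCTLNPRCITAQFGCYCTHRVCTIN,3721.55,TRUE
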