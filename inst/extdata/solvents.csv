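name,cas,molar_mass_g_mol,available,htping_x10,htpinh,ttp,atp_x1e5,gwp,odp,pcop,ar
water,7732-18-5,18.02,TRUE,,,,,,,,
DMSO,67-68-5,78.13,TRUE,1.30,0.00,0.13,6.20,0.0,0.0,11.40,0.0
DMF,68-12-2,73.09,TRUE,6.75,0.81,0.68,20.00,0.0,0.0,0.00,0.0
4FM,4394-85-8,115.13,TRUE,2.54,0.00,0.25,99.90,0.0,0.0,0.00,0.0
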