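solute,organic_solvent,x2_star,T_K,x_rep1,x_rep2,x_rep3
salicylamide,4FM,0.0,298.15,0.0031,0.0029,0.0030
salicylamide,4FM,0.2,298.15,0.121,0.118,0.124
salicylamide,4FM,0.4,298.15,0.301,0.295,0.308
salicylamide,4FM,0.6,298.15,0.381,0.376,0.380
salicylamide,4FM,0.8,298.15,0.367,0.361,0.364
salicylamide,4FM,1.0,298.15,0.352,0.347,0.349
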