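species,mcv_fl,d_um,t_calc_um,sa_calc_um2,ratio,valid
Homo sapiens (discocyte),90,7.2,2.2,136,0.3,yes
Homo sapiens (macrocyte),120,9.0,1.9,176.8,0.2,yes
Homo sapiens (leptocyte),90,8.5,1.6,150.2,0.2,yes
Homo sapiens (codocyte),60,6.0,2.1,106.4,0.4,yes
Homo sapiens (spherocyte),90,4.0,7.2,n.c.,1.8,no
Homo sapiens (HS patients),80,5.9,3.0,136.1,0.5,no
Tragulus javanicus,5.6,2.2,1.5,24.7,0.7,no
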