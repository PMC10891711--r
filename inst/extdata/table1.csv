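species,d_um,t_um,mcv_fl,vs_um3,vc_um3,vb_um3
Capra hircus (goat),4.1,1.7,23.2,36.1,22.7,22.8
Sorex araneus (shrew),4.5,1.6,24.5,48,25.9,25.9
Microtus subterraneus (pine vole),4.9,1.8,33.7,60.5,33.7,33.7
Lagurus lagurus (steppe lemming),5.1,1.8,36,68.6,36.3,36.2
Myodes glareolus (bank vole),5.1,1.9,37.6,69.5,37.8,37.8
Otomops martiensseni (free-tailed bat),5.3,1.8,40.7,77.9,39.7,39.6
Microtus agrestis (field vole),5.0,2.1,41.1,67,41.3,41.4
Sicista betulina (birch mouse),5.6,1.7,42.8,91.9,41.9,41.7
Microtus oeconomus (tundra vole),5.1,2.2,44,68.6,43.8,43.9
Mus musculus (house mouse),5.5,2.1,52.1,87.1,49.9,49.9
Bison bonasus (European bison),5.77,2.1,54.8,100.6,54.9,54.9
Rattus norvegicus (brown rat),6.3,2.1,65,130.9,65.5,65.3
Oryctolagus cuniculus (rabbit),6.3,2.3,70.4,130.9,70.8,70.7
Homo sapiens (human),7.2,2.2,90,195.4,91.6,91.3
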