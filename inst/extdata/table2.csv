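species,d_um,t_um,sa_um2,sas_um2,sac_um2,sab_um2
Capra hircus (goat),4.1,1.7,,52.8,48.6,54.4
Sorex araneus (shrew),4.5,1.6,,63.9,54.9,58.7
Microtus subterraneus (pine vole),4.9,1.8,,74.5,64.9,70.2
Lagurus lagurus (steppe lemming),5.1,1.8,,81.1,69.1,73.5
Myodes glareolus (bank vole),5.1,1.9,,81.7,70.5,75.6
Otomops martiensseni (free-tailed bat),5.3,1.8,,88.3,74.1,78.1
Microtus agrestis (field vole),5.0,2.1,,79.8,72.7,80.9
Sicista betulina (birch mouse),5.6,1.7,,98.5,79.2,81.1
Microtus oeconomus (tundra vole),5.1,2.2,,81.1,75,84.4
Mus musculus (house mouse),5.5,2.1,90.9,95,83.8,91.2
Bison bonasus (European bison),5.77,2.1,,104.6,90.4,97
Rattus norvegicus (brown rat),6.3,2.1,103,124.7,103.9,108.1
Oryctolagus cuniculus (rabbit),6.3,2.3,,124.7,107.8,114.9
Homo sapiens (human),7.2,2.2,136,162.9,132.3,136.5
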