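region,electrodes,score_mean,score_sd
Transverse temporal,TP8 T7 T8,0.660,0.01
Banks superior temporal sulcus,P8 TP7 TP8,0.735,0.01
Caudal anterior-cingulate,FC2 AFz F2,0.987,0.0006
Caudal middle frontal,FC6 FC3 FC4,0.791,0.003
Isthmus-cingulate,PO8 PO7 Pz POz,0.807,0.01
Lateral occipital,PO7 PO8 O1 O2,0.853,0.0007
Lateral orbitofrontal,N2 F8 N1 F9 F10,0.987,0.0006
Lingual gyrus,Iz PO8 PO7 Oz,0.784,0.002
Medial orbital frontal,Fp2 N2 Fpz,0.928,0.001
Paracentral lobule,C1 C2 Cpz Cz,0.931,0.001
Pars opercularis,FC5 FC6 FT7 FT8,0.684,0.003
Pars orbitalis,F8 AF7 F9 F10,0.918,0.001
Pars triangularis,FT7 FT8 F5 F8 F7,0.685,0.004
Pericalcarine,POz O1 O2 Oz,0.908,0.0005
Postcentral gyrus,T8 C5 C4 C6 C3,0.610,0.002
Posterior cingulate,Cz C1 FC2 C2,0.881,0.001
Precentral gyrus,C3 C2 C4 C1,0.821,0.001
Precuneus,PO3 Pz POz,0.951,0.0009
Rostral anterior cingulate,AF4 AFz Fp2 Fpz,0.853,0.001
Rostral middle frontal gyrus,AF3 F5 AF8 F6,0.740,0.002
Superior frontal gyrus,AF3 F5 AF8 F6,0.961,0.0004
Superior parietal,POz CP1 P2 P1,0.894,0.0007
Superior temporal gyrus,TP8 FT9 T8 T7,0.660,0.001
Supramarginal gyrus,C5 CP5 CP6,0.816,0.001
Cuneus,PO3 PO4 Oz POz,0.919,0.0009
Inferior parietal,P3 P4 P5 P6,0.842,0.002
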