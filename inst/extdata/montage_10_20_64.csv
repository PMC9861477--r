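name,x,y,z
Fp1,-0.293893,0.904508,0.309017
AF7,-0.559017,0.769421,0.309017
AF3,-0.30546,0.81019,0.500286
F1,-0.233713,0.60313,0.762635
F3,-0.449045,0.603776,0.658645
F5,-0.631664,0.58906,0.503993
F7,-0.769421,0.559017,0.309017
FT7,-0.904508,0.293893,0.309017
FC5,-0.762351,0.314502,0.565605
FC3,-0.550852,0.323783,0.769238
FC1,-0.288925,0.321723,0.901675
C1,-0.309017,0,0.951057
C3,-0.587785,0,0.809017
C5,-0.809017,0,0.587785
T7,-0.951057,0,0.309017
TP7,-0.904508,-0.293893,0.309017
CP5,-0.762351,-0.314502,0.565605
CP3,-0.550852,-0.323783,0.769238
CP1,-0.288925,-0.321723,0.901675
P1,-0.233713,-0.60313,0.762635
P3,-0.449045,-0.603776,0.658645
P5,-0.631664,-0.58906,0.503993
P7,-0.769421,-0.559017,0.309017
P9,-0.809017,-0.587785,0
PO7,-0.559017,-0.769421,0.309017
PO3,-0.30546,-0.81019,0.500286
O1,-0.293893,-0.904508,0.309017
Iz,0,-1,0
Oz,0,-0.951057,0.309017
POz,0,-0.809017,0.587785
Pz,0,-0.587785,0.809017
CPz,0,-0.309017,0.951057
Fpz,0,0.951057,0.309017
Fp2,0.293893,0.904508,0.309017
AF8,0.559017,0.769421,0.309017
AF4,0.30546,0.81019,0.500286
AFz,0,0.809017,0.587785
Fz,0,0.587785,0.809017
F2,0.233713,0.60313,0.762635
F4,0.449045,0.603776,0.658645
F6,0.631664,0.58906,0.503993
F8,0.769421,0.559017,0.309017
FT8,0.904508,0.293893,0.309017
FC6,0.762351,0.314502,0.565605
FC4,0.550852,0.323783,0.769238
FC2,0.288925,0.321723,0.901675
FCz,0,0.309017,0.951057
Cz,0,0,1
C2,0.309017,0,0.951057
C4,0.587785,0,0.809017
C6,0.809017,0,0.587785
T8,0.951057,0,0.309017
TP8,0.904508,-0.293893,0.309017
CP6,0.762351,-0.314502,0.565605
CP4,0.550852,-0.323783,0.769238
CP2,0.288925,-0.321723,0.901675
P2,0.233713,-0.60313,0.762635
P4,0.449045,-0.603776,0.658645
P6,0.631664,-0.58906,0.503993
P8,0.769421,-0.559017,0.309017
P10,0.809017,-0.587785,0
PO8,0.559017,-0.769421,0.309017
PO4,0.30546,-0.81019,0.500286
O2,0.293893,-0.904508,0.309017
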