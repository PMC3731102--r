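subject_id,landmark,x_mm,y_mm,z_mm
sim0001,CdR,59.12,0.39,0.15
sim0001,CdL,-64.72,-5.63,5.37
sim0001,GoR,54.53,11.74,-55.63
sim0001,GoL,-54.77,12.12,-54.83
sim0001,FzR,49.38,39.29,44.68
sim0001,FzL,-50.02,39.57,44.71
sim0001,KrR,56.50,39.83,10.41
sim0001,KrL,-56.49,40.07,9.80
sim0001,Me,8.96,74.99,-59.99
sim0001,N,-0.33,70.05,44.78
sim0001,Gl,-0.20,72.33,54.89
sim0001,DB,-0.44,69.52,-10.89
sim0002,CdR,60.17,-0.52,0.44
sim0002,CdL,-59.51,-0.07,-0.21
sim0002,GoR,55.26,12.06,-54.26
sim0002,GoL,-54.97,11.73,-54.86
sim0002,FzR,50.27,40.02,45.06
sim0002,FzL,-50.47,40.28,44.67
sim0002,KrR,57.41,40.02,10.04
sim0002,KrL,-57.26,40.56,9.95
sim0002,Me,-0.15,74.35,-59.99
sim0002,N,-0.19,69.95,44.89
sim0002,Gl,-0.03,72.14,55.46
sim0002,DB,-0.03,70.24,-9.62
sim0003,CdR,64.79,-6.29,5.17
sim0003,CdL,-60.75,0.40,0.03
sim0003,GoR,55.73,12.07,-55.13
sim0003,GoL,-54.61,12.14,-55.05
sim0003,FzR,49.80,39.44,44.92
sim0003,FzL,-49.79,39.92,45.28
sim0003,KrR,56.52,39.93,10.28
sim0003,KrL,-57.15,40.77,9.79
sim0003,Me,-10.63,75.06,-60.39
sim0003,N,-1.28,69.51,44.71
sim0003,Gl,0.46,72.15,55.28
sim0003,DB,0.54,70.54,-9.74
sim0004,CdR,60.01,0.52,-0.47
sim0004,CdL,-60.47,-1.12,-0.38
sim0004,GoR,54.64,11.93,-55.20
sim0004,GoL,-54.96,11.12,-54.74
sim0004,FzR,49.88,40.82,44.75
sim0004,FzL,-50.05,40.05,45.04
sim0004,KrR,56.85,39.58,10.44
sim0004,KrL,-57.53,40.23,10.06
sim0004,Me,-0.34,75.25,-60.24
sim0004,N,0.17,70.18,45.34
sim0004,Gl,-0.04,71.70,55.40
sim0004,DB,-0.38,70.86,-9.70
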