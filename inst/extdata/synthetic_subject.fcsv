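# Markups fiducial file version = 4.11
# CoordinateSystem = LPS
# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID
F1,59.12,0.39,0.15,0,0,0,1,1,1,0,CdR,sim0001,
F2,-64.72,-5.63,5.37,0,0,0,1,1,1,0,CdL,sim0001,
F3,54.53,11.74,-55.63,0,0,0,1,1,1,0,GoR,sim0001,
F4,-54.77,12.12,-54.83,0,0,0,1,1,1,0,GoL,sim0001,
F5,49.38,39.29,44.68,0,0,0,1,1,1,0,FzR,sim0001,
F6,-50.02,39.57,44.71,0,0,0,1,1,1,0,FzL,sim0001,
F7,56.50,39.83,10.41,0,0,0,1,1,1,0,KrR,sim0001,
F8,-56.49,40.07,9.80,0,0,0,1,1,1,0,KrL,sim0001,
F9,8.96,74.99,-59.99,0,0,0,1,1,1,0,Me,sim0001,
F10,-0.33,70.05,44.78,0,0,0,1,1,1,0,N,sim0001,
F11,-0.20,72.33,54.89,0,0,0,1,1,1,0,Gl,sim0001,
F12,-0.44,69.52,-10.89,0,0,0,1,1,1,0,DB,sim0001,
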