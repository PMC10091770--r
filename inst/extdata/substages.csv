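name,parent_stage,start_ma,end_ma
Zlichovian,Emsian,407.6,402.0
Dalejan,Emsian,402.0,393.3
Early Famennian,Famennian,372.2,365.6
Late Famennian,Famennian,365.6,358.9
Chadian,Visean,346.7,342.8
Arundian,Visean,342.8,339.4
Holkerian,Visean,339.4,336.0
Asbian,Visean,336.0,332.7
Brigantian,Visean,332.7,330.9
Pendleian,Serpukhovian,330.9,327.6
Arnsbergian,Serpukhovian,327.6,323.2
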