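scale,item,w,p_printed
HGS,ears,0.567,<0.001
HGS,orb,0.794,<0.001
HGS,ten,0.470,0.025
HGS,chew,0.421,0.091
HGS,mouth,0.418,0.099
HGS,nost,0.575,<0.001
EQUUS_FAP,head,0.383,<0.001
EQUUS_FAP,eye,0.433,0.068
EQUUS_FAP,focus,0.819,<0.001
EQUUS_FAP,nost,0.405,0.134
EQUUS_FAP,mouth,0.316,0.584
EQUUS_FAP,tone,0.329,0.500
EQUUS_FAP,fleya,0.751,<0.001
EQUUS_FAP,teeth,0.333,0.474
EQUUS_FAP,ears,0.376,0.242
EPS,pf,0.428,0.078
EPS,gross,0.753,<0.001
EPS,act,0.722,<0.001
EPS,loc,0.605,<0.001
EPS,pos,0.743,<0.001
EPS,head,0.409,0.122
EPS,att,0.333,0.474
EPS,int,0.775,<0.001
EPS,food,0.881,<0.001
CPS,kick,0.333,0.474
CPS,paw,0.763,<0.001
CPS,head,0.538,<0.003
CPS,app,0.646,<0.001
CPS,pos,0.741,<0.001
CPS,app2,0.837,<0.001
CPS,sweat,0.920,<0.001
CPS,int,0.333,0.474
CPS,palp,0.844,<0.001
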