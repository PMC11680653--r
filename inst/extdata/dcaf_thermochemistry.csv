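compound,species,solvent,mechanism,site,dG_rxn,dG_act
dCAF-82,neutral,pentylethanoate,f-HAT,O3a,10.52,na
dCAF-82,neutral,water,f-HAT,O3a,8.24,na
dCAF-82,mono-anion,water,f-HAT,O3a,2.59,na
dCAF-82,di-anion,water,f-HAT,O3a,-0.38,na
dCAF-82,neutral,pentylethanoate,f-HAT,O7a,-7.44,12.41
dCAF-82,neutral,water,f-HAT,O7a,-6.49,14.04
dCAF-82,mono-anion,water,f-HAT,O7a,-8.14,13.96
dCAF-82,neutral,pentylethanoate,f-HAT,O8a,-9.88,13.81
dCAF-82,neutral,water,f-HAT,O8a,-8.89,11.45
dCAF-82,mono-anion,water,f-HAT,O8a,-9.99,10.11
dCAF-82,di-anion,water,f-HAT,O8a,-15.05,barrierless
dCAF-82,neutral,pentylethanoate,RAF,C2,9.90,na
dCAF-82,neutral,water,RAF,C2,7.66,na
dCAF-82,mono-anion,water,RAF,C2,7.72,na
dCAF-82,di-anion,water,RAF,C2,4.37,na
dCAF-82,neutral,pentylethanoate,RAF,C3,10.55,na
dCAF-82,neutral,water,RAF,C3,8.08,na
dCAF-82,mono-anion,water,RAF,C3,8.34,na
dCAF-82,di-anion,water,RAF,C3,4.42,na
dCAF-82,neutral,pentylethanoate,RAF,C4,16.93,na
dCAF-82,neutral,water,RAF,C4,13.92,na
dCAF-82,mono-anion,water,RAF,C4,17.33,na
dCAF-82,di-anion,water,RAF,C4,9.70,na
dCAF-82,neutral,pentylethanoate,RAF,C5,9.77,na
dCAF-82,neutral,water,RAF,C5,8.88,na
dCAF-82,mono-anion,water,RAF,C5,12.86,na
dCAF-82,di-anion,water,RAF,C5,6.57,na
dCAF-82,neutral,pentylethanoate,RAF,C6,15.17,na
dCAF-82,neutral,water,RAF,C6,14.85,na
dCAF-82,mono-anion,water,RAF,C6,18.64,na
dCAF-82,di-anion,water,RAF,C6,11.47,na
dCAF-82,neutral,pentylethanoate,RAF,C7,8.35,na
dCAF-82,neutral,water,RAF,C7,8.57,na
dCAF-82,mono-anion,water,RAF,C7,12.72,na
dCAF-82,di-anion,water,RAF,C7,10.34,na
dCAF-82,neutral,pentylethanoate,RAF,C8,11.13,na
dCAF-82,neutral,water,RAF,C8,9.26,na
dCAF-82,mono-anion,water,RAF,C8,12.65,na
dCAF-82,di-anion,water,RAF,C8,4.43,na
dCAF-82,neutral,pentylethanoate,RAF,C9,13.59,na
dCAF-82,neutral,water,RAF,C9,11.64,na
dCAF-82,mono-anion,water,RAF,C9,17.34,na
dCAF-82,di-anion,water,RAF,C9,11.01,na
dCAF-82,neutral,water,SET,SET,25.06,na
dCAF-82,mono-anion,water,SET,SET,22.24,na
dCAF-82,di-anion,water,SET,SET,1.48,na
dCAF-2,neutral,pentylethanoate,f-HAT,O3a,11.81,na
dCAF-2,neutral,water,f-HAT,O3a,6.38,na
dCAF-2,mono-anion,water,f-HAT,O3a,3.90,na
dCAF-2,di-anion,water,f-HAT,O3a,3.57,na
dCAF-2,neutral,pentylethanoate,f-HAT,O7a,-3.70,8.10
dCAF-2,neutral,water,f-HAT,O7a,-4.23,15.20
dCAF-2,mono-anion,water,f-HAT,O7a,-6.34,14.12
dCAF-2,neutral,pentylethanoate,f-HAT,O8a,-2.78,17.77
dCAF-2,neutral,water,f-HAT,O8a,-3.41,15.72
dCAF-2,mono-anion,water,f-HAT,O8a,-4.83,15.39
dCAF-2,di-anion,water,f-HAT,O8a,-12.09,barrierless
dCAF-2,neutral,water,SET,SET,32.17,na
dCAF-2,mono-anion,water,SET,SET,33.37,na
dCAF-2,di-anion,water,SET,SET,3.37,na
dCAF-16,neutral,pentylethanoate,f-HAT,O7a,-3.47,16.99
dCAF-16,neutral,water,f-HAT,O7a,-3.87,16.80
dCAF-16,mono-anion,water,f-HAT,O7a,-6.45,14.54
dCAF-16,neutral,pentylethanoate,f-HAT,O8a,-1.77,15.80
dCAF-16,neutral,water,f-HAT,O8a,-2.73,14.85
dCAF-16,mono-anion,water,f-HAT,O8a,-4.41,6.86
dCAF-16,di-anion,water,f-HAT,O8a,-10.89,barrierless
dCAF-16,neutral,water,SET,SET,33.67,na
dCAF-16,mono-anion,water,SET,SET,29.70,na
dCAF-16,di-anion,water,SET,SET,4.24,na
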