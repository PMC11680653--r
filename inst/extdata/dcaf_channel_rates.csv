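compound,solvent,species,site,k
dCAF-2,pentylethanoate,neutral,O7a,3.45e3
dCAF-2,pentylethanoate,neutral,O8a,1.98e2
dCAF-2,water,neutral,O7a,1.08e4
dCAF-2,water,neutral,O8a,8.88e3
dCAF-2,water,mono-anion,O7a,3.58e4
dCAF-2,water,mono-anion,O8a,5.30e3
dCAF-2,water,di-anion,O8a,7.86e9
dCAF-16,pentylethanoate,neutral,O7a,1.81e3
dCAF-16,pentylethanoate,neutral,O8a,1.92e3
dCAF-16,water,neutral,O7a,2.98e3
dCAF-16,water,neutral,O8a,1.96e4
dCAF-16,water,mono-anion,O7a,5.08e4
dCAF-16,water,mono-anion,O8a,6.77e4
dCAF-16,water,di-anion,O8a,8.03e9
dCAF-82,pentylethanoate,neutral,O7a,8.04e4
dCAF-82,pentylethanoate,neutral,O8a,5.87e3
dCAF-82,water,neutral,O7a,1.69e5
dCAF-82,water,neutral,O8a,4.43e5
dCAF-82,water,mono-anion,O7a,9.39e4
dCAF-82,water,mono-anion,O8a,2.97e6
dCAF-82,water,di-anion,O8a,7.98e9
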