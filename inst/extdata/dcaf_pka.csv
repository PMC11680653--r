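compound,pka1,pka2,pka3,pka4
dCAF-16,3.33,7.58,11.92,na
dCAF-82,3.72,8.11,12.25,12.43
dCAF-2,3.66,7.94,12.22,13.33
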