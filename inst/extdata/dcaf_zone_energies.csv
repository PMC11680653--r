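compound,prep_forward,transition_forward,prep_reverse,transition_reverse
dCAF-2,4.95,0.94,10.15,6.22
dCAF-16,5.53,0.87,9.26,6.98
dCAF-82,3.79,0.52,8.87,9.37
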