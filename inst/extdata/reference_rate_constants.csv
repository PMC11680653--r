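species_id,solvent,k
caffeic_acid,pentylethanoate,3.93e4
caffeic_acid,water,2.69e8
trolox,water,8.96e4
ferulic_acid,water,3.36e8
p-coumaric_acid,water,8.51e7
dihydrocaffeic_acid,water,1.04e8
lipid_peroxidation_propagation,lipid,1.18e3
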