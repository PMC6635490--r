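organ,reference_mass_g
gallbladder_wall,10.5
heart_wall,316
kidney,299
liver,1910
lung,999
pancreas,94.3
spleen,183
stomach_wall,158
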