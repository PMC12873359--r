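animal_id,group,sex,age_weeks,weight_g
14030,VPA,M,252,416.7
14031,VPA,M,252,431.3
16017,VPA,M,161,507.0
16043,VPA,M,152,410.6
17024,VPA,M,104,364.9
14078,UE,M,226,382.7
15033,UE,M,200,393.1
15034,UE,M,200,397.6
15050,UE,M,187,422.5
16089,UE,M,139,543.5
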