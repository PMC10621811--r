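comparison,age_group,reference_test,a,b,c,d
cancellation,5-8,TBCT,8,3,24,18
cancellation,9-12,SLCT,3,0,5,55
cancellation,13-18,SLCT,6,2,8,17
condition,5-8,known_condition,18,3,7,6
condition,9-12,known_condition,8,7,0,21
condition,13-18,known_condition,8,3,1,4
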