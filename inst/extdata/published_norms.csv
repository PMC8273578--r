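tool,hemisphere,age,level,threshold
FS,left,56,5,3223
FS,left,90,5,2506
FS,right,56,5,3456
FS,right,90,5,2415
AA,left,56,5,4583
AA,left,90,5,3831
AA,right,56,5,4873
AA,right,90,5,3870
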