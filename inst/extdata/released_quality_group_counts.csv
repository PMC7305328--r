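quality_group,n_slides
Best,2346
Good,1246
Adequate,593
Problematic,302
Unacceptable,573
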