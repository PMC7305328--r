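quality_group,n_patch_labels
Best,446
Good,242
Adequate,128
Problematic,52
Unacceptable,103
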