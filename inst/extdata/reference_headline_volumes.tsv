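metric	value
execution_voxels	11229
imagery_voxels	16194
working_memory_voxels	27724
pct_imagery_with_wm	60
pct_imagery_with_ex	28
pct_difference	42
matched_target_voxels	11229
matched_imagery_voxels	11215
matched_working_memory_voxels	11228
matched_pct_imagery_with_wm	36
matched_pct_imagery_with_ex	32
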