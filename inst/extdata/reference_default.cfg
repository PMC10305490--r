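# Default modified 45S rDNA reference geometry (1-based closed coordinates).
# Last 1,979 bp of the canonical repeat joined to its first 14,000 bp.
total_length 15979
segment 18S 5636 7506
segment 28S 9914 14948
window 18S 6986 7135
window 28S 11564 11713
exclusion 5636 6535
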