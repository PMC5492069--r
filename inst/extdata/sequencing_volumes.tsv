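sample	raw_pairs	raw_bases	norm_pairs	norm_bases
2nd	213817714	42763542800	13268461	2653692200
4th	222117185	44423437000	15199439	3039887800
female	205127388	41025477600	11786560	2357312000
male	218215787	43643157400	14191526	2838305200
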