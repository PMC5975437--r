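species	cls	total	supported	grand_total	grand_supported
human	trans	78	5	13646	110
human	ribo	613	18	13646	110
human	noribo	746	2	13646	110
human	other	12209	85	13646	110
mouse	trans	42	7	6260	52
mouse	ribo	367	10	6260	52
mouse	noribo	326	2	6260	52
mouse	other	5525	33	6260	52
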