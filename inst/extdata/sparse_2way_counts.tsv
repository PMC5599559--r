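genotype	case	control
0-0	50	60
0-1	50	5
0-2	0	1
1-0	5	5
1-1	0	80
1-2	0	0
2-0	240	50
2-1	18	31
2-2	30	35
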