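compound	n_neurons	is_reference	1e-12	1e-11	1e-10	1e-09	1e-08	1e-07	1e-06
3a	5	FALSE	–	96 ± 4	90 ± 5	83 ± 4	79 ± 5	76 ± 5	56 ± 5
3b	5	FALSE	–	–	100 ± 1	100 ± 3	100 ± 2	100 ± 2	100 ± 3
3c	5	FALSE	–	–	100 ± 1	100 ± 3	100 ± 2	100 ± 2	100 ± 3
3d	3	FALSE	100 ± 3	100 ± 3	106 ± 4	120 ± 6	127 ± 6	119 ± 5	103 ± 3
3e	3	FALSE	100 ± 2	100 ± 3	89 ± 4	77 ± 6	71 ± 5	88 ± 4	97 ± 3
3f	3	FALSE	100 ± 4	95 ± 4	88 ± 6	78 ± 6	86 ± 5	92 ± 4	99 ± 2
3g	4	FALSE	125 ± 5	147 ± 6	156 ± 7	168 ± 7	134 ± 4	113 ± 4	105 ± 3
3h	3	FALSE	100 ± 2	116 ± 4	143 ± 5	153 ± 5	159 ± 6	142 ± 5	121 ± 4
3i	4	FALSE	100 ± 3	117 ± 4	118 ± 5	118 ± 5	120 ± 6	122 ± 6	109 ± 5
3j	3	FALSE	100 ± 3	139 ± 8	177 ± 10	163 ± 11	146 ± 8	141 ± 10	138 ± 9
I	4	TRUE	141 ± 7	172 ± 9	152 ± 7	144 ± 5	129 ± 4	113 ± 4	105 ± 3
CTZ	8	TRUE	–	–	–	–	–	100 ± 3	145 ± 11
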