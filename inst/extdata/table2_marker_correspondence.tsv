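marker_a	map_a_cM	status_a	marker_b	map_b_cM	status_b	match_type
E707X	0	X	Contig4232	4.3	X	same-gene
SlX4	4.2	X	Contig8519	14.5	X	same-gene
SIX6A	5.4	X	Contig14178	13.4	X	scaffold-colocated
SlX7	7.7	X	Contig842	18.2	X	same-gene
E711X	14.1	X	NA	NA	NA	none
SlX3	28.1	X	NA	NA	NA	none
E713X	36.3	X	Contig19016	35.7	X	scaffold-colocated
E807X	44.5	X	NA	NA	NA	none
E330X	60.5	X	NA	NA	NA	none
SlCypX	67.9	X	Contig8805	52.6	X	same-gene
SIX9	67.9	X	NA	NA	NA	none
E777X	71.4	X	Contig3001	60.9	X	same-gene
E779X	71.4	X	Contig675	62.6	X	scaffold-colocated
cs1536X	81.5	X	NA	NA	NA	none
E799X	82.6	X	NA	NA	NA	none
cs3597	83.8	PAR	NA	NA	NA	none
E780X	83.8	PAR	Contig8488	62.7	X	same-gene
E316X	83.8	PAR	NA	NA	NA	none
E559X	83.8	PAR	NA	NA	NA	none
E521X	83.8	PAR	NA	NA	NA	none
E523X	83.8	PAR	NA	NA	NA	none
cs32X	84.9	PAR	Contig16105	65.7	PAR	scaffold-colocated
E247X	84.9	PAR	NA	NA	NA	none
SlX6B	84.9	PAR	NA	NA	NA	none
SlCyt	84.9	PAR	NA	NA	NA	none
E200	86.1	PAR	NA	NA	NA	none
cs1539	86.1	PAR	NA	NA	NA	none
E241	86.1	PAR	Contig3920	72.1	PAR	same-gene
cs4991	86.1	PAR	Contig7492	76.2	PAR	same-gene
E352X	85.5	PAR	Contig4019	80.6	PAR	scaffold-colocated
E592	101.3	PAR	Contig11138	89.7	PAR	scaffold-colocated
cs5136X	120.6	PAR	NA	NA	NA	none
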