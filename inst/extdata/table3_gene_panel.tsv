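gene_id	map_cM	cross_status	region_label	y_snps_analyzed	y_snps_in_females	n_females_with_y
Contig675	62.6	X	X	0	NA	NA
Contig697	62.6	X	X	5	0	0
Contig804	62.6	X	X	0	NA	NA
Contig867	62.6	X	X	0	NA	NA
Contig8509	62.6	X	X	0	NA	NA
Contig8660	62.6	X	X	0	NA	NA
Contig15301	62.6	X	X	1	0	0
Contig1564	62.6	X	X	0	NA	NA
Contig1740	62.6	X	X	0	NA	NA
Contig17645	62.6	X	X	0	NA	NA
Contig18491	62.6	X	X	0	NA	NA
Contig1290	62.6	X	X	0	NA	NA
Contig1436	62.6	X	X	0	NA	NA
Contig15401	62.6	X	X	0	NA	NA
Contig12513	62.6	X	X	3	0	0
Contig1804	62.6	X	X	0	NA	NA
Contig18911	62.6	X	X	0	NA	NA
Contig2431	62.6	X	X	0	NA	NA
Contig2761	62.6	X	X	0	NA	NA
Contig2802	62.6	X	X	0	NA	NA
Contig3835	62.6	X	X	0	NA	NA
Contig14349	62.6	X	X	17	0	0
Contig3846	62.6	X	X	0	NA	NA
Contig4210	62.6	X	X	0	NA	NA
Contig4518	62.6	X	X	0	NA	NA
Contig17773	62.6	X	X	27	0	0
Contig5724	62.6	X	X	0	NA	NA
Contig8598	62.6	X	X	11	0	0
Contig1798	62.7	X	fuzzy-I	4	1	1
Contig8488	62.7	X	fuzzy-I	0	NA	NA
Contig9505	62.7	X	fuzzy-I	14	1	3
Contig18786	62.7	X	fuzzy-I	2	0	0
Contig255	62.7	X	fuzzy-I	0	NA	NA
Contig12476	62.8	X	fuzzy-I	0	NA	NA
Contig2117	62.9	X	fuzzy-I	1	0	0
Contig1858	62.9	X	fuzzy-I	0	NA	NA
Contig456	62.9	X	fuzzy-I	0	NA	NA
Contig1229	63.0	X	fuzzy-I	0	NA	NA
Contig6406	63.0	X	fuzzy-I	0	NA	NA
Contig1046	63.4	X	fuzzy-II	13	4	3
Contig1251	63.4	X	fuzzy-II	24	4	3
Contig13504	63.4	X	fuzzy-II	5	0	0
Contig1623	63.4	X	fuzzy-II	3	0	0
Contig528	63.4	X	fuzzy-II	11	0	0
Contig13419	63.6	X	fuzzy-II	23	4	2
Contig15757	63.6	X	fuzzy-II	13	0	0
Contig15519	63.6	X	fuzzy-II	2	0	0
Contig9011	63.6	X	fuzzy-II	1	1	3
Contig16617	64.8	PAR	PAR	0	NA	NA
Contig3920	72.1	PAR	PAR	0	NA	NA
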