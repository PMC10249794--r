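genotype_id	accession	clade
#1	AB067721	GC
#2	synthetic	GC
#3	synthetic	GC
#4	AB067744	AT_CLUSTER_B
#5	AB067740	AT_CLUSTER_A
#6	EU555436	AT_CLUSTER_A
#7	synthetic	GC
#8	synthetic	GC
#9	synthetic	GC
#10	synthetic	GC
#11	synthetic	GC
#12	synthetic	GC
#13	synthetic	GC
#14	synthetic	GC
#15	synthetic	AT_CLUSTER_B
#16	KT232019	AT_CLUSTER_A
#17	synthetic	AT_CLUSTER_A
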