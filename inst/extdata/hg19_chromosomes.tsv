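name	length	centromere
chr1	249250621	123035434
chr2	243199373	93826171
chr3	198022430	92004854
chr4	191154276	51160117
chr5	180915260	47905641
chr6	171115067	60330166
chr7	159138663	59554331
chr8	146364022	45338887
chr9	141213431	48867679
chr10	135534747	40754935
chr11	135006516	53144205
chr12	133851895	36356694
chr13	115169878	17500000
chr14	107349540	17500000
chr15	102531392	18500000
chr16	90354753	36835801
chr17	81195210	23763006
chr18	78077248	16960898
chr19	59128983	26181782
chr20	63025520	27869569
chr21	48129895	12788129
chr22	51304566	14500000
chrX	155270560	60132012
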