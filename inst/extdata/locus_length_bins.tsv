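# gene-locus span length bins (worked-example input)
# loci_total is the stated overall locus count; the bin counts sum to a
# slightly different value in the source table, so shares are taken over
# loci_total
bin	n	loci_total
<1k	2096	30670
1-2k	8975	30670
2-3k	8682	30670
>3k	10971	30670
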