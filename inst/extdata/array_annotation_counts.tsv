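category	count
Annotation possible	58340
Nonsense-mediated decay (NMD)	19
Loss of function (LOF)	114
Intergenic region	12156
Intragenic variant	126
Intron variant	21581
Missense variant	8765
Missense variant & splice region variant	263
Stop gained	16
Stop lost	13
Synonymous variant	1142
Non-coding transcript exon variant	27
Splice acceptor variant & intron variant	9
Splice donor variant & intron variant	13
Splice region variant	8
Splice region variant & intron variant	163
Splice region variant & non-coding transcript exon variant	7
Splice region variant & synonymous variant	28
Upstream gene variant	9231
3 prime UTR variant	1533
5 prime UTR premature start codon gain variant	21
5 prime UTR variant	459
Downstream gene variant	2646
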