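# Small training set of literature-style RNA secondary structures used to
# seed the default grammar parameters by counting (name, sequence, structure;
# tab separated). Structures exercise hairpins, left/right bulges, internal
# loops, three-, four- and five-way junctions, in roughly the proportions
# seen in structured RNAs (loops far more common than junctions).
hp1	GGGGAAAACCCC	((((....))))
hp2	GCGCGUUAAGCGC	(((((...)))))
hp3	GGGGGUUCGCCCCC	(((((....)))))
hp4	GGGGAAACCCC	((((...))))
bulgeL1	GGGAGGGGUUUUCCCCCCC	(((.((((....)))))))
bulgeL2	GGAGGGGAAACCCCCC	((.((((...))))))
bulgeL3	CCAGGGAAAACCCGG	((.(((....)))))
bulgeL4	GGGAAGGGUUUCCCCCC	(((..(((...))))))
bulgeL5	GGGGAGGGAAACCCCCCC	((((.(((...)))))))
bulgeR1	GGGGGGAAAACCCCAACC	((((((....))))..))
bulgeR2	GGGGGAAACCCAACC	(((((...)))..))
bulgeR3	GGGGGGAAAACCCCACC	((((((....)))).))
bulgeR4	GGGGGGAAACCCAACCC	((((((...)))..)))
bulgeR5	GGGGGGGAAACCCACCCC	(((((((...))).))))
intloop1	GGGGAAGGGGUUUUCCCCAAACCCC	((((..((((....))))...))))
intloop2	GGGGAGGGGUUUUCCCCAACCCC	((((.((((....))))..))))
intloop3	CCCAAGGGAAAACCCAAAGGG	(((..(((....)))...)))
intloop4	GGAAGGGUUUCCCAACC	((..(((...)))..))
intloop5	GGGGAGGGAAAACCCAACCCC	((((.(((....)))..))))
intloop6	GGGAGGGAAACCCUCCC	(((.(((...))).)))
intloop7	GGAAAGGGUUUCCCAACC	((...(((...)))..))
intloop8	GGGAAGGGGAAAACCCCACCC	(((..((((....)))).)))
j3a	CCCAGGGAAACCCAAGGGUUUCCCAGGG	(((.(((...)))..(((...))).)))
j4a	GGAGGGUUUCCCAGGGAAACCCAGGGUUUCCCACC	((.(((...))).(((...))).(((...))).))
j5a	GGAGGGAAACCCAGGGUUUCCCAGGGAAACCCAGGGUUUCCCACC	((.(((...))).(((...))).(((...))).(((...))).))
ext1	AAGGGUUUCCCAAGGGAAACCCAA	..(((...)))..(((...)))..
ext2	AAGGGAAAACCCAAAGGGUUUCCC	..(((....)))...(((...)))
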