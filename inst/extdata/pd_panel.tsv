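rank	pathway_name
1	Transcription/translation
2	Dopa-responsive dystonia
3	Fatty acid elongation in mitochondria
4	Long-chain-3-hydroxyacyl-coa dehydrogenase deficiency (LCHAD)
5	Hyperphenylalaninemia due to guanosine triphosphate cyclohydrolase deficiency
6	Hyperphenylalaninemia due to 6-pyruvoyltetrahydropterin synthase (PTPS) deficiency
7	Hyperphenylalaninemia due to DHPR deficiency
8	Pterine biosynthesis
9	Segawa syndrome
10	Sepiapterin reductase deficiency
11	Warburg effect
12	Glutaminolysis and cancer
13	Mercaptopurine action pathway
14	Thioguanine action pathway
15	Glycine and serine metabolism
16	AICA-ribosiduria
17	Adenine phosphoribosyltransferase deficiency (APRT)
18	Adenosine deaminase deficiency
19	Lesch-Nyhan Syndrome (LNS)
20	Mitochondrial DNA depletion syndrome
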