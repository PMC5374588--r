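1	naproxen	NN	3	nsubjpass
2	was	VBD	3	auxpass
3	given	VBN	0	root
4	for	IN	6	case
5	liver	NN	6	compound
6	injury	NN	3	nmod
7	.	.	3	punct

1	metformin	NN	3	nsubj
2	-	HYPH	3	punct
3	induced	VBN	0	root
4	liver	NN	5	compound
5	injury	NN	3	dobj
6	.	.	3	punct

1	the	DT	2	det
2	patient	NN	3	nsubj
3	developed	VBD	0	root
4	rhabdomyolysis	NN	3	dobj
5	after	IN	6	mark
6	taking	VBG	3	advcl
7	acetylsalicylic	NN	8	compound
8	acid	NN	6	dobj
9	.	.	3	punct

1	the	DT	2	det
2	patient	NN	3	nsubj
3	developed	VBD	0	root
4	skin	NN	5	compound
5	rash	NN	3	dobj
6	after	IN	7	mark
7	taking	VBG	3	advcl
8	valproic	NN	9	compound
9	acid	NN	7	dobj
10	.	.	3	punct

1	the	DT	2	det
2	patient	NN	3	nsubj
3	developed	VBD	0	root
4	nephritis	NN	3	dobj
5	after	IN	6	mark
6	taking	VBG	3	advcl
7	fusidic	NN	8	compound
8	acid	NN	6	dobj
9	.	.	3	punct

1	fusidic	NN	2	compound
2	acid	NN	4	nsubjpass
3	was	VBD	4	auxpass
4	given	VBN	0	root
5	for	IN	6	case
6	hypoglycemia	NN	4	nmod
7	.	.	4	punct
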