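##gff-version 3
# Synthetic mini-annotation of a chrXIII segment for testing gene reporting.
# Gene names are real yeast gene symbols but ALL coordinates are synthetic:
# the six genes of the mapped-locus center are placed inside the central half
# of the interval 247,466-277,019, with flanking genes outside it.
##sequence-region chrXIII 1 350000
chrXIII	synthetic	gene	240000	241500	.	+	.	ID=YML020W;Name=YML020W
chrXIII	synthetic	gene	249000	250500	.	-	.	ID=YML008C;Name=YML008C
chrXIII	synthetic	gene	255000	256500	.	-	.	ID=YML006C;Name=GIS4
chrXIII	synthetic	gene	257000	258200	.	-	.	ID=YML005C;Name=TRM12
chrXIII	synthetic	gene	259000	260000	.	-	.	ID=YML004C;Name=GLO1
chrXIII	synthetic	gene	261000	262800	.	+	.	ID=YML002W;Name=YML002W
chrXIII	synthetic	gene	263500	264700	.	+	.	ID=YML003W;Name=YML003W
chrXIII	synthetic	gene	266000	266700	.	+	.	ID=YML001W;Name=YPT7
chrXIII	synthetic	gene	270500	272000	.	-	.	ID=YML015C;Name=YML015C
chrXIII	synthetic	gene	280000	281500	.	+	.	ID=YML030W;Name=YML030W
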