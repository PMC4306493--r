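step_index	substrate	product	core_enzymes	branch_enzymes
1	glucose	glucose-6-phosphate	HK1
2	glucose-6-phosphate	fructose-6-phosphate	GPI	G6PD;PGM1
3	fructose-6-phosphate	fructose-1,6-bisphosphate	PFKL	GFPT1
4	fructose-1,6-bisphosphate	dihydroxyacetone-phosphate	ALDOA
5	dihydroxyacetone-phosphate	glyceraldehyde-3-phosphate	TPI1	GPD1
6	glyceraldehyde-3-phosphate	1,3-bisphosphoglycerate	GAPDH
7	1,3-bisphosphoglycerate	3-phosphoglycerate	PGK1
8	3-phosphoglycerate	2-phosphoglycerate	PGAM1	PHGDH
9	2-phosphoglycerate	phosphoenolpyruvate	ENO1
10	phosphoenolpyruvate	pyruvate	PKM
11	pyruvate	lactate	LDHA	PC;PDHA1
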