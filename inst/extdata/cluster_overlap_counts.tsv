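annotation	n_rnaseq_specific	n_array_specific	n_common	shared
Hair follicle	76	10	62	TRUE
Sebaceous gland	17	229	105	TRUE
Eccrine sweat gland	62	79	101	TRUE
Apocrine gland	25	0	25	FALSE
Keratinocyte differentiation	48	114	78	TRUE
Keratinocyte (subset)	4	4	7	TRUE
Melanocyte	1	10	7	TRUE
Fibroblast	69	160	132	TRUE
Endothelium	150	18	40	TRUE
Smooth muscle	49	19	49	TRUE
Skeletal muscle	64	0	64	FALSE
Adipocyte	10	21	30	TRUE
Macrophage/DC	45	39	49	TRUE
T cell	29	13	17	TRUE
FceR signalling	9	0	7	TRUE
Plasma cell	2	17	7	TRUE
IFN	21	5	22	TRUE
Cell cycle (S/M)	69	8	65	TRUE
Circadian clock	0	8	8	FALSE
Y-chromosome	3	1	13	TRUE
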