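variant_id	pah_type	sex	age_at_diagnosis	functional_class	pap	rap	cardiac_index	pvr_wu	t6mw_m	dlco_percent	survival_years	final_status
c.211C>T	CHD_associated	Male	24	III	150/70/90	12	2.5	18.5	484	NA	4	Alive
c.298G>A	PVOD	Male	58	III	47	2	3.5	6.7	180	22.5	4.5	Exitus
c.1429G>A	IPAH	Male	32	III	62/27/39	12	2	12	276	92	22.5	Alive
c.1643C>T	IPAH	Female	27	II	96/36/58	9	2.55	10	525	63	8	Alive
c.2176G>A	HPAH	Male	36	III	136/55/91	4	2.15	9.25	525	100	7	Transplant
c.2422C>A	IPAH	Female	34	III	45/18/29	4	2.9	4	420	72	12	Alive
c.2694+1G>A	CTD_associated	Female	26	III	125/48/78	4	3.57	12.9	463	74	18	Alive
c.3238G>A	IPAH	Female	43	II	114/26/55	9	2.7	13.2	336	73	18	Alive
c.3288_3289del	IPAH	Female	29	III	69/33/45	6	3.94	6.6	562	92	9	Alive
c.3394G>A	CHD_associated	Female	NA	II	57/26/38	10	1.65	8.27	366	NA	4	Alive
c.3976G>A	IPAH	Male	31	NA	100/66/77	6	2.3	13.2	266	74	18	Alive
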