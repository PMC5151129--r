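rank	molecule_a	molecule_b	score	log10_p	auc	r1	r2
1	hsa-miR-191	hsa-miR-590-5p	0.963	-3.76	0.880	0.764	-0.200
2	hsa-miR-125b	hsa-miR-18a	0.930	-3.55	0.733	-0.218	0.712
3	hsa-miR-140-3p	hsa-miR-191	0.921	-2.85	0.800	0.540	-0.381
4	hsa-miR-103	hsa-miR-19b	0.917	-3.56	0.797	0.776	-0.141
5	hsa-miR-192	hsa-miR-197	0.912	-3.61	0.867	-0.281	0.631
6	hsa-miR-191	hsa-miR-19b	0.911	-4.10	0.854	0.826	-0.085
7	hsa-miR-152	hsa-miR-191	0.892	-3.42	0.863	0.772	-0.121
8	hsa-miR-103	hsa-miR-590-5p	0.888	-3.24	0.749	0.614	-0.275
9	hsa-miR-191	hsa-miR-320a	0.873	-3.38	0.872	0.691	-0.182
10	hsa-miR-125b	hsa-miR-20a	0.871	-3.80	0.801	-0.090	0.781
11	hsa-miR-106a	hsa-miR-125b	0.869	-3.94	0.785	-0.083	0.786
12	hsa-miR-101	hsa-miR-103	0.865	-3.65	0.768	0.805	-0.060
13	hsa-miR-125b	hsa-miR-24	0.840	-3.42	0.801	-0.073	0.768
14	hsa-miR-101	hsa-miR-191	0.831	-3.96	0.871	0.822	-0.009
15	hsa-miR-103	hsa-miR-222	0.828	-3.24	0.745	0.622	-0.207
16	hsa-miR-197	hsa-miR-378	0.820	-2.78	0.810	-0.234	0.586
17	hsa-miR-103	hsa-miR-223	0.815	-3.79	0.786	0.840	0.025
18	hsa-miR-125b	hsa-miR-223	0.815	-3.49	0.765	-0.015	0.800
19	hsa-let-7b	hsa-miR-125b	0.811	-3.75	0.718	-0.056	0.755
20	hsa-miR-125b	hsa-miR-484	0.801	-3.52	0.739	-0.078	0.723
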