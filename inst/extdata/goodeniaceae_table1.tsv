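species_id	clade	subjective_label	n_images	pc1_mean	pc2_mean	cluster_mean	kmeans_majority
Brunonia australis	outgroup	fan	12	0.303	0.004	1.00	fan
Coopernookia georgei	Goodenia_sl	bilabiate	1	-0.332	-0.085	2.00	pseudo_radial
Coopernookia polygalacea	Goodenia_sl	pseudo_radial	5	-0.207	-0.041	2.00	pseudo_radial
Coopernookia strophiolata	Goodenia_sl	bilabiate	8	-0.083	0.101	3.00	bilabiate
Dampiera lindleyi	outgroup	bilabiate	9	-0.332	-0.129	2.00	pseudo_radial
Diaspasis filifolia	Scaevola_sl	bilabiate	13	-0.159	-0.074	2.08	pseudo_radial
Goodenia berardiana	Goodenia_sl	pseudo_radial	6	-0.088	-0.115	2.00	pseudo_radial
Goodenia convexa	Goodenia_sl	pseudo_radial	6	-0.242	-0.128	2.00	pseudo_radial
Goodenia berringbinensis	Goodenia_sl	bilabiate	14	-0.170	0.082	2.79	bilabiate
Goodenia decursiva	Goodenia_sl	fan	9	0.190	0.110	1.00	fan
Goodenia disperma	Goodenia_sl	bilabiate	1	-0.240	-0.102	2.00	pseudo_radial
Goodenia drummondii	Goodenia_sl	fan	9	0.314	0.005	1.00	fan
Goodenia filiformis	Goodenia_sl	pseudo_radial	9	-0.129	-0.038	2.22	pseudo_radial
Goodenia hassallii	Goodenia_sl	bilabiate	9	-0.332	-0.006	2.44	pseudo_radial
Goodenia helmsii	Goodenia_sl	fan	9	0.300	-0.012	1.00	fan
Goodenia macmillanii	Goodenia_sl	bilabiate	1	-0.366	-0.016	2.00	pseudo_radial
Goodenia micrantha	Goodenia_sl	bilabiate	9	-0.188	0.008	2.56	bilabiate
Goodenia mimuloides	Goodenia_sl	pseudo_radial	6	-0.162	-0.019	2.33	pseudo_radial
Goodenia occidentalis	Goodenia_sl	pseudo_radial	4	-0.221	-0.063	2.25	pseudo_radial
Goodenia ovata	Goodenia_sl	bilabiate	10	-0.278	-0.035	2.10	pseudo_radial
Goodenia phillipsiae	Goodenia_sl	bilabiate	4	-0.304	0.207	3.00	bilabiate
Goodenia pinifolia	Goodenia_sl	bilabiate	9	-0.145	0.193	2.78	bilabiate
Goodenia pusilliflora	Goodenia_sl	bilabiate	11	-0.240	0.002	2.45	pseudo_radial
Goodenia stephensonii	Goodenia_sl	bilabiate	2	-0.211	0.143	3.00	bilabiate
Goodenia tripartita	Goodenia_sl	bilabiate	9	-0.217	-0.069	2.00	pseudo_radial
Goodenia varia	Goodenia_sl	bilabiate	11	-0.304	0.140	3.00	bilabiate
Goodenia viscida	Goodenia_sl	fan	7	0.286	0.011	1.00	fan
Scaevola anchusifolia	Scaevola_sl	fan	11	0.319	0.047	1.00	fan
Scaevola calliptera	Scaevola_sl	pseudo_radial	6	-0.001	-0.020	1.67	pseudo_radial
Scaevola canescens	Scaevola_sl	fan	5	0.345	-0.040	1.00	fan
Scaevola collaris	Goodenia_sl	fan	9	0.376	-0.066	1.00	fan
Scaevola crassifolia	Scaevola_sl	fan	6	0.307	-0.022	1.00	fan
Scaevola humifusa	Scaevola_sl	fan	5	0.341	-0.026	1.00	fan
Scaevola phlebopetala	Scaevola_sl	fan	10	0.150	0.017	1.00	fan
Scaevola platyphylla	Scaevola_sl	fan	9	0.302	-0.036	1.00	fan
Scaevola porocarya	Scaevola_sl	fan	9	0.258	0.033	1.00	fan
Scaevola spinescens	Scaevola_sl	fan	11	0.312	0.025	1.00	fan
Scaevola thesioides	Scaevola_sl	fan	5	0.272	0.005	1.00	fan
Scaevola tomentosa	Scaevola_sl	fan	10	0.386	-0.030	1.00	fan
Selliera radicans	Goodenia_sl	fan	1	0.136	0.066	1.00	fan
Velleia cycnopotamica	Goodenia_sl	pseudo_radial	4	0.018	-0.114	1.75	pseudo_radial
Velleia discophora	Goodenia_sl	bilabiate	5	-0.272	0.213	3.00	bilabiate
Velleia foliosa	Goodenia_sl	pseudo_radial	9	-0.265	-0.168	2.00	pseudo_radial
Velleia rosea	Goodenia_sl	pseudo_radial	8	-0.084	-0.131	2.00	pseudo_radial
Verreauxia reinwardtii	Goodenia_sl	bilabiate	9	-0.288	0.070	3.00	bilabiate
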