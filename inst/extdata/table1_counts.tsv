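group	taxid	n_hit_species	n_total_species	printed_pct	digits
Bacteria	2	295	38842	0.76	2
Cyanobacteria	1117	56	506	11.07	2
Actinobacteria	201174	136	4870	2.79	2
Proteobacteria	1223	69	16196	0.43	2
Eukaryotes	2759	406	2241	18.12	2
Animals (Metazoa)	33208	229	612	37.42	2
Insects	50557	0	142	0.00	2
Worms (Annelida)	6340	0	2	0.00	2
Fungi	4751	177	1098	16.12	2
Yeast (Ascomycota)	4890	176	760	23.16	2
Yeast (Saccharomyces)	4930	0	13	0.00	2
Plants (Viridiplantae)	33090	0	244	0.00	2
Opisthokonta (metazoa and fungi)	33208|4751	406	1710	23.74	2
Pre-opisthokonta (eukarya, not metazoa or fungi)	2759-not-33208|4751	0	531	0.00	2
Archaea	2157	1	2107	0.05	2
Viruses	10239	1	99210	0.001	3
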