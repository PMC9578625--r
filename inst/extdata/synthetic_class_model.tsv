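# SYNTHETIC fixture defaults: plausible random-coil-like chemical shift means
# (ppm) for disordered proteins, used only by the simulation module.  These
# numbers are hand-rounded typical values, NOT database statistics, and must
# never be used as reference random-coil shifts in real analyses.
# NA marks shifts that are structurally absent (Gly CB/HB, Pro HN).
# freq: approximate relative abundance of each residue type in proteins.
residue	freq	HN	N	CO	CA	CB	HA	HB
A	0.083	8.25	123.8	177.8	52.5	19.1	4.32	1.39
R	0.055	8.27	120.5	176.3	56.0	30.9	4.34	1.79
N	0.041	8.40	118.7	175.2	53.1	38.9	4.74	2.80
D	0.055	8.34	120.4	176.3	54.2	41.1	4.64	2.68
C	0.014	8.32	118.8	174.6	58.2	28.0	4.55	2.95
Q	0.039	8.32	119.8	176.0	55.7	29.4	4.34	2.05
E	0.067	8.42	120.7	176.6	56.6	30.0	4.35	2.01
G	0.071	8.33	108.8	174.9	45.1	NA	3.96	NA
H	0.023	8.42	118.9	174.8	55.0	29.0	4.73	3.15
I	0.059	8.00	120.4	176.4	61.1	38.8	4.17	1.87
L	0.096	8.16	121.8	177.6	55.1	42.4	4.34	1.62
K	0.058	8.29	120.4	176.6	56.2	33.1	4.32	1.80
M	0.024	8.28	119.6	176.3	55.4	32.9	4.48	2.05
F	0.039	8.30	120.3	175.8	57.7	39.6	4.62	3.10
P	0.047	NA	137.0	177.3	63.3	32.1	4.42	2.05
S	0.066	8.31	116.6	174.6	58.3	63.8	4.47	3.87
T	0.054	8.24	115.5	174.7	61.8	69.8	4.35	4.22
W	0.011	8.09	121.3	176.1	57.5	29.6	4.66	3.25
Y	0.029	8.12	120.3	175.9	57.9	38.8	4.55	2.98
V	0.069	8.03	120.4	176.3	62.2	32.9	4.12	2.05
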