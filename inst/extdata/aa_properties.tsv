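residue	hydropathy	mol_weight	volume	polarity	isoelectric	helix_prop	sheet_prop	net_charge
A	1.8	89.09	88.6	8.1	6.00	1.42	0.83	0
C	2.5	121.16	108.5	5.5	5.07	0.70	1.19	0
D	-3.5	133.10	111.1	13.0	2.77	1.01	0.54	-1
E	-3.5	147.13	138.4	12.3	3.22	1.51	0.37	-1
F	2.8	165.19	189.9	5.2	5.48	1.13	1.38	0
G	-0.4	75.07	60.1	9.0	5.97	0.57	0.75	0
H	-3.2	155.16	153.2	10.4	7.59	1.00	0.87	0.1
I	4.5	131.17	166.7	5.2	6.02	1.08	1.60	0
K	-3.9	146.19	168.6	11.3	9.74	1.16	0.74	1
L	3.8	131.17	166.7	4.9	5.98	1.21	1.30	0
M	1.9	149.21	162.9	5.7	5.74	1.45	1.05	0
N	-3.5	132.12	114.1	11.6	5.41	0.67	0.89	0
P	-1.6	115.13	112.7	8.0	6.30	0.57	0.55	0
Q	-3.5	146.15	143.8	10.5	5.65	1.11	1.10	0
R	-4.5	174.20	173.4	10.5	10.76	0.98	0.93	1
S	-0.8	105.09	89.0	9.2	5.68	0.77	0.75	0
T	-0.7	119.12	116.1	8.6	5.60	0.83	1.19	0
V	4.2	117.15	140.0	5.9	5.96	1.06	1.70	0
W	-0.9	204.23	227.8	5.4	5.89	1.08	1.37	0
Y	-1.3	181.19	193.6	6.2	5.66	0.69	1.47	0
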