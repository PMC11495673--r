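# Per-amino-acid physicochemical scales, version 1.
# Columns (sources chosen by the package; values are configuration data):
#   hydrophilicity        Hopp & Woods (1981)
#   flexibility           Bhaskaran & Ponnuswamy (1988) average flexibility
#   accessibility         Janin (1979) interior-to-surface transfer energy
#   turn_propensity       Chou & Fasman (1978) beta-turn propensity
#   exposed_surface       Rose et al. (1985) mean area buried on transfer (A^2)
#   antigenicity          Welling et al. (1985) antigenic propensity
#   net_charge_index      NCISC, Klein et al.-derived side-chain charge index
#   polarizability        Charton & Charton (1982)
#   hydrophobicity_h11a   Kyte & Doolittle (1982)
#   hydrophobicity_h12a   Eisenberg et al. (1984) consensus
#   polarity_p11a         Grantham (1974)
#   polarity_p12a         Zimmerman et al. (1968)
#   side_chain_volume     residue volume (A^3), Zamyatnin (1972)
aa	hydrophilicity	flexibility	accessibility	turn_propensity	exposed_surface	antigenicity	net_charge_index	polarizability	hydrophobicity_h11a	hydrophobicity_h12a	polarity_p11a	polarity_p12a	side_chain_volume
A	-0.5	0.357	0.3	0.66	86.6	0.115	0.007187	0.046	1.8	0.62	8.1	0.00	88.6
R	3.0	0.529	-1.4	0.95	162.2	0.058	0.043587	0.291	-4.5	-2.53	10.5	52.00	173.4
N	0.2	0.463	-0.5	1.56	103.3	-0.077	0.005392	0.134	-3.5	-0.78	11.6	3.38	114.1
D	3.0	0.511	-0.6	1.46	97.8	0.065	-0.023820	0.105	-3.5	-0.90	13.0	49.70	111.1
C	-1.0	0.346	0.9	1.19	132.3	-0.120	-0.036610	0.128	2.5	0.29	5.5	1.48	108.5
Q	0.2	0.493	-0.7	0.98	119.2	-0.011	0.049211	0.180	-3.5	-0.85	10.5	3.53	143.8
E	3.0	0.497	-0.7	0.74	113.9	-0.071	0.006802	0.151	-3.5	-0.74	12.3	49.90	138.4
G	0.0	0.544	0.3	1.56	62.9	-0.184	0.179052	0.000	-0.4	0.48	9.0	0.00	60.1
H	-0.5	0.323	-0.1	0.95	155.8	0.312	-0.010690	0.230	-3.2	-0.40	10.4	51.60	153.2
I	-1.8	0.462	0.7	0.47	158.0	-0.292	0.021631	0.186	4.5	1.38	5.2	0.13	166.7
L	-1.8	0.365	0.5	0.59	164.1	0.075	0.051672	0.186	3.8	1.06	4.9	0.13	166.7
K	3.0	0.466	-1.8	1.01	115.5	0.206	0.017708	0.219	-3.9	-1.50	11.3	49.50	168.6
M	-1.3	0.295	0.4	0.60	172.9	-0.385	0.002683	0.221	1.9	0.64	5.7	1.43	162.9
F	-2.5	0.314	0.5	0.60	194.1	-0.141	0.037552	0.290	2.8	1.19	5.2	0.35	189.9
P	0.0	0.509	-0.3	1.52	92.9	-0.053	0.239531	0.131	-1.6	0.12	8.0	1.58	112.7
S	0.3	0.507	-0.1	1.43	85.6	-0.026	0.004627	0.062	-0.8	-0.18	9.2	1.67	89.0
T	-0.4	0.444	-0.2	0.96	106.5	-0.045	0.003352	0.108	-0.7	-0.05	8.6	1.66	116.1
W	-3.4	0.305	0.3	0.96	224.6	-0.114	0.037977	0.409	-0.9	0.81	5.4	2.10	227.8
Y	-2.3	0.420	-0.4	1.14	177.7	0.013	0.023599	0.298	-1.3	0.26	6.2	1.61	193.6
V	-1.5	0.386	0.6	0.50	141.0	-0.013	0.057004	0.140	4.2	1.08	5.9	0.13	140.0
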