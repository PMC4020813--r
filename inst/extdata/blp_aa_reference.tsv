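# Reference per-residue values for the bioluminescent-protein (BLP) analysis:
# amino-acid propensity scores from the published SCMBLP card and amino-acid
# composition (%) of the BLP and non-BLP training classes.
residue	score	comp_blp	comp_nonblp
A	359.750	7.12	8.15
C	572.850	2.09	1.28
D	498.100	5.82	5.55
E	404.075	6.25	6.79
F	548.075	4.58	3.90
G	573.025	7.53	6.49
H	534.450	2.75	2.33
I	456.525	5.60	5.66
K	336.275	5.14	5.80
L	426.700	9.31	9.70
M	483.150	2.42	2.27
N	451.125	4.23	4.21
P	472.950	4.99	4.91
Q	435.025	3.70	4.03
R	384.875	4.96	5.51
S	368.500	6.61	7.27
T	452.750	5.51	5.40
V	477.775	6.60	6.45
W	434.575	1.22	1.27
Y	508.750	3.56	3.05
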