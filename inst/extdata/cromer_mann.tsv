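# Cromer-Mann X-ray atomic form-factor coefficients (International Tables
# for Crystallography Vol. C, four-Gaussian parametrisation):
#   f(q) = c + sum_{k=1..4} a_k * exp(-b_k * (q / 4 pi)^2),  q in A^-1, b in A^2
# volume_nm3: solvent-displaced atomic volume (Fraser dummy-atom convention).
# table version: 1
element	a1	a2	a3	a4	b1	b2	b3	b4	c	z	volume_nm3
H	0.493002	0.322912	0.140191	0.040810	10.5109	26.1257	3.14236	57.7997	0.003038	1	0.00515
C	2.310000	1.020000	1.588600	0.865000	20.8439	10.2075	0.568700	51.6512	0.215600	6	0.01644
N	12.212600	3.132200	2.012500	1.166300	0.005700	9.893300	28.997500	0.582600	-11.529000	7	0.00249
O	3.048500	2.286800	1.546300	0.867000	13.2771	5.701100	0.323900	32.9089	0.250800	8	0.00913
Na	4.762600	3.173600	1.267400	1.112800	3.285000	8.842200	0.313600	129.424000	0.676000	11	0.00445
P	6.434500	4.179100	1.780000	1.490800	1.906700	27.157000	0.526000	68.164500	1.114900	15	0.00573
S	6.905300	5.203400	1.437900	1.586300	1.467900	22.215100	0.253600	56.172000	0.866900	16	0.01986
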