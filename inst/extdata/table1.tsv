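# E. coli alkaline phosphatase kcat/KM (M^-1 s^-1) for all 32 combinations of
# the five active-site residues D101, R166, D153, E322 (Mg2+), K328.
# Mutant aliases: D101A, R166S, D153A, E322Y, K328A. Bracketed (model-derived)
# entries carry provenance=calculated; the quadruple mutant retaining only
# D153 is an upper limit (censor=le). km in uM, kcat in s^-1.
# wt_observed = 3.3e+07
# wt_chem_limited = 6.3e+08
variant	kcat_km	stderr	censor	provenance	km	kcat
WT	3.3e+07		none	measured	3.6e-01	1.2e+01
D101A	9.9e+06	2.0e+06	none	measured	3.6e+00	3.6e+01
R166S	1.0e+05		none	measured	5.0e+00	5.0e-01
D153A	2.8e+06	4.0e+05	none	measured	2.6e+00	7.6e+00
E322Y	7.2e+03	2.2e+03	none	measured	5.0e-01
K328A	7.5e+05	2.4e+05	none	measured	5.4e+00	3.4e+00
D101A/R166S	5.8e+04	2.0e+03	none	measured	8.4e+00	4.2e-01
D101A/D153A	3.3e+05	7.0e+04	none	measured	6.2e+00	2.2e+00
D101A/E322Y	3.1e+00	1.0e-01	none	measured	1.5e+02	4.6e-04
D101A/K328A	2.8e+04		none	calculated
R166S/D153A	1.3e+04	1.0e+03	none	measured	5.3e+00	7.0e-02
R166S/E322Y	1.6e+00	5.0e-01	none	measured	2.7e+01
R166S/K328A	2.4e+02	4.0e+01	none	measured	6.3e+01	1.6e-02
D153A/E322Y	2.3e+03	1.0e+02	none	measured	5.2e-01	1.4e-03
D153A/K328A	4.4e+05	1.4e+05	none	measured	2.4e+00	1.1e+00
E322Y/K328A	1.5e+03	1.0e+02	none	measured	2.2e+00	3.4e-03
D101A/R166S/D153A	2.0e+04	7.0e+03	none	measured	4.8e+00	8.3e-02
D101A/R166S/E322Y	4.2e-02		none	calculated
D101A/R166S/K328A	2.8e+02		none	calculated
D101A/D153A/E322Y	1.3e+01		none	calculated
D101A/D153A/K328A	1.2e+05	1.0e+04	none	measured	1.1e+01	1.6e+00
D101A/E322Y/K328A	1.1e+00	1.0e-01	none	measured	7.8e+01	8.9e-05
R166S/D153A/E322Y	1.9e+01	1.0e+00	none	measured	4.4e+02	8.3e-03
R166S/D153A/K328A	3.6e+03	1.0e+02	none	measured	7.2e+00	2.6e-02
R166S/E322Y/K328A	3.9e-01	8.0e-02	none	measured	1.4e+02	5.7e-05
D153A/E322Y/K328A	3.2e+02	3.0e+01	none	measured	2.1e+00	7.3e-04
D101A/R166S/D153A/E322Y	9.4e-01	1.6e-01	none	measured	3.5e+02	3.2e-04
D101A/R166S/D153A/K328A	5.5e+03	1.7e+03	none	measured	1.2e+01	6.1e-02
D101A/R166S/E322Y/K328A	2.0e-02		le	measured
D101A/D153A/E322Y/K328A	2.0e+00	1.0e-01	none	measured	1.4e+02	2.4e-04
R166S/D153A/E322Y/K328A	4.4e+00	1.0e-01	none	measured	2.2e+02	9.6e-04
D101A/R166S/D153A/E322Y/K328A	1.7e-01	3.0e-02	none	measured	1.6e+02	2.9e-05
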