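aa	p1	p2	p3	p4	p5	p6	p7	p8	p9	p10	p11
A	0.619428	0.629145	0.105702	0.286772	0.022799	0.217391	0.061918	0.793294	0.803976	0.898136	0.318919
C	0.641713	0.115421	0.42815	0.465866	0.314829	0.124193	0.953536	0.51319	0.220359	0.629892	0.305286
D	0.986969	0.615838	0.592931	0.263881	0.772222	0.668597	0.435728	0.712197	0.841186	0.792532	0.251561
E	0.5315	0.968037	0.514578	0.101257	0.660681	0.772656	0.27159	0.862963	0.907981	0.916885	0.646426
F	0.409773	0.73514	0.83089	0.091106	0.25596	0.453181	0.464296	0.816938	0.365469	0.65491	0.256925
G	0.646513	0.053816	0.516131	0.059451	0.837972	0.308943	0.189777	0.877092	0.251603	0.19855	0.635581
H	0.331849	0.844496	0.731643	0.041134	0.312749	0.610608	0.669854	0.069205	0.725094	0.36117	0.065782
I	0.766867	0.231509	0.38492	0.229299	0.153028	0.924557	0.215819	0.798807	0.192329	0.619288	0.989176
K	0.30605	0.696372	0.229233	0.294617	0.018555	0.897358	0.641821	0.013053	0.453881	0.473254	0.33798
L	0.720986	0.487162	0.508078	0.930498	0.614955	0.817115	0.798396	0.013487	0.752409	0.951707	0.044295
M	0.130092	0.914635	0.199501	0.900402	0.412467	0.570106	0.779475	0.737721	0.622599	0.903337	0.023953
N	0.115765	0.280418	0.805723	0.607209	0.843804	0.683731	0.582411	0.25865	0.312011	0.656235	0.153496
P	0.932171	0.545886	0.197359	0.044571	0.15631	0.346463	0.737138	0.916176	0.978371	0.490707	0.148081
Q	0.657245	0.109439	0.429871	0.547713	0.814155	0.913717	0.337196	0.707539	0.326012	0.056084	0.610292
R	0.903414	0.54104	0.950002	0.965075	0.065701	0.764356	0.333665	0.957895	0.959692	0.26457	0.310048
S	0.130679	0.280005	0.985269	0.609066	0.428573	0.818128	0.1615	0.907077	0.302975	0.305654	0.87846
T	0.895947	0.963596	0.797124	0.08377	0.608002	0.858908	0.697167	0.177043	0.155678	0.700048	0.934673
V	0.632119	0.151634	0.746846	0.374598	0.34847	0.844186	0.872801	0.518618	0.307786	0.050085	0.379035
W	0.453873	0.779035	0.06201	0.781115	0.892401	0.149051	0.958	0.339081	0.615346	0.223549	0.944712
Y	0.172753	0.381329	0.538859	0.419714	0.71393	0.601413	0.47438	0.861693	0.979561	0.622197	0.8304
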