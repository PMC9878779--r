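gene	p	q_published	gwas_overlap
MAP3K1	4.61e-22	8.28e-18	yes
FAM72B	1.32e-15	1.19e-11	yes
SRGAP2C	1.01e-14	6.07e-11	yes
TNNT3	6.17e-08	2.77e-04	yes
LSP1	1.31e-07	4.70e-04	yes
FGFR2	9.48e-07	2.84e-03	yes
MIER3	2.81e-06	7.22e-03	yes
FMNL3	6.11e-06	1.37e-02	no
KCNN4	1.12e-05	2.03e-02	yes
BTN2A1	1.26e-05	2.03e-02	yes
LYPD5	1.39e-05	2.03e-02	yes
ABRAXAS1	1.40e-05	2.03e-02	yes
AC058822.1	1.47e-05	2.03e-02	no
ZNF404	2.23e-05	2.86e-02	yes
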