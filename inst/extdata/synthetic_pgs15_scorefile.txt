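# Synthetic PGS-Catalog-format scoring file (15 variants) for tests and
# examples. Weights are made up; the layout mirrors PGS Catalog flat files.
#pgs_id=PGSSYNTH01
#genome_build=GRCh38
rsID	chr_name	chr_position	effect_allele	other_allele	effect_weight
rs0001	1	10230421	A	G	0.052
rs0002	1	88156923	T	C	-0.031
rs0003	2	19045871	G	A	0.118
rs0004	3	4742251	C	T	0.064
rs0005	4	84370124	A	C	-0.089
rs0006	5	1279790	T	G	0.143
rs0007	6	151949806	C	A	0.027
rs0008	8	128077146	G	T	0.095
rs0009	9	110303808	A	G	-0.012
rs0010	10	123340431	T	C	0.171
rs0011	11	69331642	C	G	0.201
rs0012	12	28174817	G	A	0.033
rs0013	14	37132769	A	T	-0.047
rs0014	16	52599188	T	A	0.084
rs0015	22	40876234	C	T	0.059
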