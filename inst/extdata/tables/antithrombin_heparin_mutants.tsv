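# Antithrombin - heparin pentasaccharide mutant energetics (literature Kd
# values; dG_ES/dG_DS columns are continuum-solver outputs treated as
# data). Units: energies kcal/mol, Kd nM.
# comparator: reference variant for the observed ddG (RT ln Kd ratio).
# es_ds_comparator: reference variant for the ddG_ES / ddG_DS columns
# (the three N135A-background double mutants are referenced to N135A).
# kd_external: Kd derived from an external calorimetric reference rather
# than direct titration; its printed ddG_OBS is not recovered by the
# RT ln ratio at 298 K.
label	dG_ES	ddG_ES	dG_DS	ddG_DS	Kd_nM	ddG_OBS	comparator	es_ds_comparator	kd_external
Wt	-199.8	0	184.6	0	6	0	Wt	Wt	0
K125Q	-125.1	74.7	116.6	-68.0	12	0.4	Wt	Wt	0
K136T	-200.0	-0.25	185.0	0.4	6	0	Wt	Wt	0
N135A	-198.9	0.8	183.7	-0.9	2	-0.6	Wt	Wt	0
N135A/R129Q	-150.7	48.2	139.2	-45.4	1800	3.4	Wt	N135A	0
N135A/R129H	-151.7	47.2	139.8	-43.9	820	2.9	Wt	N135A	0
N135A/K114A	-85.4	113.5	80.2	-103.5	1800000	7.6	Wt	N135A	1
R132M	-156.7	43.0	145.2	-39.4	89	1.6	Wt	Wt	0
K133M	-159.4	40.4	147.0	-37.6	171	2.0	Wt	Wt	0
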