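file	md5
ground_truth.tsv	489be20218e5a664f4682e2988768333
metadata.csv	5ca6aefaf3c9aee25492df3fd5db4e3d
taxon_table_P01.tsv	67e01a871698e72debc59e6a18787103
taxon_table_P02.tsv	b5e3207792c2537fd60f09cf46894d76
taxon_table_P03.tsv	76f6742b7498c184b33028482ae3bd27
taxon_table_P04.tsv	7d4fd26c5f8ec3188068a0db0ccadbf0
taxon_table_P05.tsv	4f59de8766f43284655650b4c0a3063e
taxon_table_P06.tsv	24eeed2b162ade589f1f0d7c610b009e
taxon_table_P07.tsv	efb4b9b3d1c96ec754117b9d170a52ec
taxon_table_P08.tsv	17ef45800b498cec8d9615ae98f8a4e3
taxon_table_P09.tsv	7c0e360da4642e9f4a36752861d71358
taxon_table_P10.tsv	3a1f2d47d5883f9d97dc39b5c5e1e5d2
taxon_table_P11.tsv	0475d064e612f44d5f7042b6d47bfa15
taxon_table_P12.tsv	989b46b44af3b236dccf8e6e08b370e2
cohort_statistics.tsv	211b67e316f34a6bbd5902315e18375f
cohort_summary.tsv	0634f80961dde6c6683a4f7eed658f30
colonization.tsv	cc1a75b206f040185d2d4c623e9274be
dunn_pairwise.tsv	31fbf207ba9cf77a353a249ea5276dc0
fine_scale.tsv	18d68ba3043464c70316c924bb8d8b5b
lung_function_fits.tsv	221637aa70b833e15d9096ce0e8b088a
onset_summary.tsv	a9f77238b54c655ee577986fe5e4a952
onset.tsv	e9bc6f50f18c62512cb7a31f46259794
patient_status.tsv	19202aeb40854d044cff6f39e2bd16f1
str_fits.tsv	242555ca34e13793eca46229a87c1bd6
taxon_counts.tsv	91f2e692886031522e47534dc09345b9
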