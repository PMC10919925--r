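# Published per-type variant counts in organelle protein-coding genes of
# Brassica triangle-of-U allotetraploids versus the three diploid genomes.
# type: candidate genome the variant state matches (Private = matches none).
# count for genome rows equals synonymous + nonsynonymous; Private splits
# are not published for most columns and are left NA.
allopolyploid	compartment	type	synonymous	nonsynonymous	count
AABB_tumida	plastid	A-like	486	358	844
AABB_tumida	plastid	B-like	0	0	0
AABB_tumida	plastid	C-like	0	0	0
AABB_tumida	plastid	Private	NA	NA	0
AABB_tumida	mitochondrion	A-like	13	30	43
AABB_tumida	mitochondrion	B-like	0	0	0
AABB_tumida	mitochondrion	C-like	0	0	0
AABB_tumida	mitochondrion	Private	NA	NA	0
AABB_varuna	plastid	A-like	486	358	844
AABB_varuna	plastid	B-like	0	0	0
AABB_varuna	plastid	C-like	0	0	0
AABB_varuna	plastid	Private	NA	NA	0
AABB_varuna	mitochondrion	A-like	13	30	43
AABB_varuna	mitochondrion	B-like	0	0	0
AABB_varuna	mitochondrion	C-like	0	0	0
AABB_varuna	mitochondrion	Private	NA	NA	0
BBCC	plastid	A-like	0	0	0
BBCC	plastid	B-like	497	374	871
BBCC	plastid	C-like	0	0	0
BBCC	plastid	Private	NA	NA	14
BBCC	mitochondrion	A-like	0	0	0
BBCC	mitochondrion	B-like	12	31	43
BBCC	mitochondrion	C-like	0	0	0
BBCC	mitochondrion	Private	NA	NA	0
AACC_Darmor-bzh	plastid	A-like	2	3	5
AACC_Darmor-bzh	plastid	B-like	0	0	0
AACC_Darmor-bzh	plastid	C-like	33	33	66
AACC_Darmor-bzh	plastid	Private	NA	NA	63
AACC_Darmor-bzh	mitochondrion	A-like	0	1	1
AACC_Darmor-bzh	mitochondrion	B-like	0	0	0
AACC_Darmor-bzh	mitochondrion	C-like	1	0	1
AACC_Darmor-bzh	mitochondrion	Private	NA	NA	0
AACC_ZS11	plastid	A-like	2	3	5
AACC_ZS11	plastid	B-like	0	0	0
AACC_ZS11	plastid	C-like	33	33	66
AACC_ZS11	plastid	Private	NA	NA	63
AACC_ZS11	mitochondrion	A-like	0	1	1
AACC_ZS11	mitochondrion	B-like	0	0	0
AACC_ZS11	mitochondrion	C-like	1	0	1
AACC_ZS11	mitochondrion	Private	NA	NA	0
AACC_No2127	plastid	A-like	2	3	5
AACC_No2127	plastid	B-like	0	0	0
AACC_No2127	plastid	C-like	33	33	66
AACC_No2127	plastid	Private	NA	NA	66
AACC_No2127	mitochondrion	A-like	1	1	2
AACC_No2127	mitochondrion	B-like	0	0	0
AACC_No2127	mitochondrion	C-like	0	0	0
AACC_No2127	mitochondrion	Private	NA	NA	0
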