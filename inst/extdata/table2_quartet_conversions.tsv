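# Published genome-wide directional gene-conversion counts per functional
# category for the three allotetraploids (quartet similarity rule).
# m_to_p: maternal sequence fixed into the paternal homoeolog;
# p_to_m: the reverse.
allopolyploid	category	m_to_p	p_to_m
AABB_tumida	Other	18	31
AABB_tumida	Dual	0	3
AABB_tumida	pt_tar	4	5
AABB_tumida	pt_int	0	0
AABB_tumida	pt_com	1	1
AABB_tumida	mt_tar	0	0
AABB_tumida	mt_int	1	2
AABB_tumida	mt_com	0	0
AABB_varuna	Other	2	0
AABB_varuna	Dual	0	1
AABB_varuna	pt_tar	1	1
AABB_varuna	pt_int	0	0
AABB_varuna	pt_com	0	0
AABB_varuna	mt_tar	0	0
AABB_varuna	mt_int	0	0
AABB_varuna	mt_com	1	0
BBCC	Other	32	38
BBCC	Dual	0	3
BBCC	pt_tar	1	3
BBCC	pt_int	0	0
BBCC	pt_com	0	0
BBCC	mt_tar	6	1
BBCC	mt_int	0	0
BBCC	mt_com	0	0
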