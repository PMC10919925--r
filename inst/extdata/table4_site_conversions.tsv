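# Published per-gene-family diagnostic-SNP counts and directional
# synonymous/nonsynonymous site-conversion counts for the nuclear gene
# families of mitochondrial complex III (subunits without detectable
# parental SNPs omitted). snps: genome-specific SNPs between the parents
# of the cross.
allopolyploid	family	snps	m_to_p_syn	m_to_p_nonsyn	p_to_m_syn	p_to_m_nonsyn
AABB_tumida	MPP-alpha	229	7	2	4	1
AABB_tumida	MPP-beta	194	6	0	2	2
AABB_tumida	QCR7	35	0	0	0	0
AABB_tumida	QCR9	8	0	0	0	0
AABB_tumida	QCR8	19	1	1	0	0
AABB_tumida	UCR1	203	21	4	1	1
AABB_tumida	QCR6	29	4	0	0	0
AABB_tumida	CYC1	45	1	0	0	0
AABB_varuna	MPP-alpha	229	7	3	3	2
AABB_varuna	MPP-beta	194	6	0	1	0
AABB_varuna	QCR7	35	0	0	0	0
AABB_varuna	QCR9	8	0	0	0	0
AABB_varuna	QCR8	19	6	4	1	0
AABB_varuna	UCR1	203	25	3	5	1
AABB_varuna	QCR6	29	3	0	0	0
AABB_varuna	CYC1	45	1	0	1	0
BBCC	MPP-alpha	252	8	9	0	1
BBCC	MPP-beta	215	8	2	5	0
BBCC	QCR7	40	0	0	1	0
BBCC	QCR9	9	0	0	0	0
BBCC	QCR8	8	1	0	2	0
BBCC	UCR1	259	27	0	27	2
BBCC	QCR6	34	0	0	3	1
BBCC	CYC1	28	0	0	2	0
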