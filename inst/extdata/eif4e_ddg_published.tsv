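protein_id	buffer_tag	from_ligand	to_ligand	ddg	ddg_se
heIF4E1a	standard	GTP	m7GTP	-4.555	0.05
heIF4E1a	standard	GTP	et7GTP	-3.59	0.028
heIF4E1a	standard	m7GTP	et7GTP	0.965	0.045
heIF4E1a	standard	m7GDP	bn7GDP	0.033	0.022
heIF4E1a	standard	m7GTP	m227GTP	3.052	0.045
heIF4E1a	standard	m7GMP	m7GDP	-1.82	0.028
heIF4E1a	standard	m7GDP	m7GTP	-0.785	0.045
heIF4E1a	standard	m7GTP	m7Gp4	-1.055	0.054
heIF4E1a	standard	m7Gp4	m7Gp5	-0.155	0.046
heIF4E1a	standard	m7GTP	m7GpppG	1.423	0.058
heIF4E1a	standard	m7GTP	m7GpppA	1.658	0.053
heIF4E1a	standard	m7GpppG	m7G2OpppG	-0.018	0.05
heIF4E1a	standard	m7GpppG	m7Gpppm2OG	0.128	0.041
heIF4E1b	standard	GTP	m7GTP	-2.87	0.15
heIF4E1b	standard	GTP	et7GTP	-2.23	0.15
heIF4E1b	standard	m7GTP	et7GTP	0.639	0.045
heIF4E1b	standard	m7GDP	bn7GDP	-0.893	0.06
heIF4E1b	standard	m7GTP	m227GTP	2.557	0.041
heIF4E1b	standard	m7GMP	m7GDP	-1.455	0.056
heIF4E1b	standard	m7GDP	m7GTP	-0.616	0.065
heIF4E1b	standard	m7GTP	m7Gp4	-0.817	0.044
heIF4E1b	standard	m7Gp4	m7Gp5	-0.287	0.047
heIF4E1b	standard	m7GTP	m7GpppG	1.065	0.04
heIF4E1b	standard	m7GTP	m7GpppA	1.352	0.039
heIF4E1b	standard	m7GpppG	m7G2OpppG	-0.157	0.022
heIF4E1b	standard	m7GpppG	m7Gpppm2OG	-0.006	0.021
XeIF4E1a	standard	GTP	m7GTP	-4.2	0.12
XeIF4E1a	standard	GTP	et7GTP	-3.21	0.13
XeIF4E1a	standard	m7GTP	et7GTP	0.984	0.05
XeIF4E1a	standard	m7GDP	bn7GDP	0.042	0.059
XeIF4E1a	standard	m7GTP	m227GTP	2.897	0.051
XeIF4E1a	standard	m7GMP	m7GDP	-1.748	0.028
XeIF4E1a	standard	m7GDP	m7GTP	-0.769	0.037
XeIF4E1a	standard	m7GTP	m7Gp4	-1.067	0.035
XeIF4E1a	standard	m7Gp4	m7Gp5	-0.202	0.071
XeIF4E1a	standard	m7GTP	m7GpppG	1.382	0.032
XeIF4E1a	standard	m7GTP	m7GpppA	1.779	0.029
XeIF4E1a	standard	m7GpppG	m7G2OpppG	NA	NA
XeIF4E1a	standard	m7GpppG	m7Gpppm2OG	NA	NA
XeIF4E1a	glycerol10	GTP	m7GTP	-3.52	0.23
XeIF4E1a	glycerol10	GTP	et7GTP	-2.62	0.23
XeIF4E1a	glycerol10	m7GTP	et7GTP	0.9	0.035
XeIF4E1a	glycerol10	m7GDP	bn7GDP	-0.006	0.096
XeIF4E1a	glycerol10	m7GTP	m227GTP	2.844	0.042
XeIF4E1a	glycerol10	m7GMP	m7GDP	-1.832	0.054
XeIF4E1a	glycerol10	m7GDP	m7GTP	-0.794	0.043
XeIF4E1a	glycerol10	m7GTP	m7Gp4	-1.087	0.04
XeIF4E1a	glycerol10	m7Gp4	m7Gp5	-0.244	0.086
XeIF4E1a	glycerol10	m7GTP	m7GpppG	1.351	0.028
XeIF4E1a	glycerol10	m7GTP	m7GpppA	1.717	0.033
XeIF4E1a	glycerol10	m7GpppG	m7G2OpppG	0.091	0.074
XeIF4E1a	glycerol10	m7GpppG	m7Gpppm2OG	0.026	0.018
XeIF4E1bdN27	glycerol10	GTP	m7GTP	NA	NA
XeIF4E1bdN27	glycerol10	GTP	et7GTP	NA	NA
XeIF4E1bdN27	glycerol10	m7GTP	et7GTP	0.722	0.059
XeIF4E1bdN27	glycerol10	m7GDP	bn7GDP	-0.341	0.044
XeIF4E1bdN27	glycerol10	m7GTP	m227GTP	2	0.11
XeIF4E1bdN27	glycerol10	m7GMP	m7GDP	NA	NA
XeIF4E1bdN27	glycerol10	m7GDP	m7GTP	-0.679	0.048
XeIF4E1bdN27	glycerol10	m7GTP	m7Gp4	-0.994	0.041
XeIF4E1bdN27	glycerol10	m7Gp4	m7Gp5	-0.246	0.046
XeIF4E1bdN27	glycerol10	m7GTP	m7GpppG	1.268	0.037
XeIF4E1bdN27	glycerol10	m7GTP	m7GpppA	1.479	0.05
XeIF4E1bdN27	glycerol10	m7GpppG	m7G2OpppG	NA	NA
XeIF4E1bdN27	glycerol10	m7GpppG	m7Gpppm2OG	NA	NA
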