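# Default single-copy marker COG set: 54 COGs, 30 flagged ribosomal.
# Synthetic stand-in membership (real COG families of the stated kind).
cog	is_ribosomal
COG0048	TRUE
COG0049	TRUE
COG0051	TRUE
COG0052	TRUE
COG0080	TRUE
COG0081	TRUE
COG0087	TRUE
COG0088	TRUE
COG0089	TRUE
COG0090	TRUE
COG0091	TRUE
COG0092	TRUE
COG0093	TRUE
COG0094	TRUE
COG0096	TRUE
COG0097	TRUE
COG0098	TRUE
COG0099	TRUE
COG0100	TRUE
COG0102	TRUE
COG0103	TRUE
COG0184	TRUE
COG0185	TRUE
COG0186	TRUE
COG0197	TRUE
COG0198	TRUE
COG0199	TRUE
COG0200	TRUE
COG0255	TRUE
COG0256	TRUE
COG0012	FALSE
COG0016	FALSE
COG0018	FALSE
COG0060	FALSE
COG0085	FALSE
COG0086	FALSE
COG0124	FALSE
COG0143	FALSE
COG0172	FALSE
COG0201	FALSE
COG0202	FALSE
COG0215	FALSE
COG0495	FALSE
COG0522	FALSE
COG0525	FALSE
COG0533	FALSE
COG0541	FALSE
COG0552	FALSE
COG0442	FALSE
COG0459	FALSE
COG0504	FALSE
COG0532	FALSE
COG0621	FALSE
COG0653	FALSE
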