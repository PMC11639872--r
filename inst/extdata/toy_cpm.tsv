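# Toy 5-gene CPM matrix used to pin the expression filter
# (>2 CPM in at least two libraries, strict inequality).
# Hand count: g1 passes (10, 5), g2 fails (only 2.1 > 2), g3 fails
# (2.0 is not > 2), g4 passes (3.0, 2.5), g5 fails (one library only).
# Survivor set: {g1, g4}.
gene_id	lib1	lib2	lib3	lib4
g1	10.0	5.0	0.0	0.0
g2	2.1	1.9	0.0	0.0
g3	2.0	2.0	2.0	2.0
g4	0.0	0.0	3.0	2.5
g5	100.0	0.0	0.0	0.0
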