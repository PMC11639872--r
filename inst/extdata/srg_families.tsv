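# Synthetic example stress-response-gene family catalog.
# Each family is defined by one or more characteristic PFAM-style domain
# accessions; category groups families by the stress axis they respond to
# (chemical, pathogen, wounding). This is a small documented placeholder,
# not an exhaustive cnidarian SRG domain list: supply your own table for
# real analyses (same three columns; accessions comma-separated; file order
# sets assignment priority for multi-family genes).
family	category	accessions
HSP70	chemical	PF00012
HSP20	chemical	PF00011
SOD	chemical	PF00081,PF02777,PF00080
glutathione_S_transferase	chemical	PF02798,PF00043
cytochrome_P450	chemical	PF00067
ferritin	chemical	PF00210
glycosyl_hydrolase	pathogen	PF00704
C_type_lectin	pathogen	PF00059
caspase_CARD	pathogen	PF00619
TNF	wounding	PF00229
thrombospondin	wounding	PF00090
von_Willebrand_A	wounding	PF00092
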