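# ZD98 manifest TEMPLATE for the apaacsvm package.
# Two tab-separated columns: class<TAB>accession.
# The accessions below are SYNTHETIC placeholders that only reproduce the
# published per-class counts; the real UniProt accessions are not printed
# in the source describing this benchmark and must be transcribed from the
# prior publications that defined it before using the fetch helper.
Cyto	ZD98_CYTO_001
Cyto	ZD98_CYTO_002
Cyto	ZD98_CYTO_003
Cyto	ZD98_CYTO_004
Cyto	ZD98_CYTO_005
Cyto	ZD98_CYTO_006
Cyto	ZD98_CYTO_007
Cyto	ZD98_CYTO_008
Cyto	ZD98_CYTO_009
Cyto	ZD98_CYTO_010
Cyto	ZD98_CYTO_011
Cyto	ZD98_CYTO_012
Cyto	ZD98_CYTO_013
Cyto	ZD98_CYTO_014
Cyto	ZD98_CYTO_015
Cyto	ZD98_CYTO_016
Cyto	ZD98_CYTO_017
Cyto	ZD98_CYTO_018
Cyto	ZD98_CYTO_019
Cyto	ZD98_CYTO_020
Cyto	ZD98_CYTO_021
Cyto	ZD98_CYTO_022
Cyto	ZD98_CYTO_023
Cyto	ZD98_CYTO_024
Cyto	ZD98_CYTO_025
Cyto	ZD98_CYTO_026
Cyto	ZD98_CYTO_027
Cyto	ZD98_CYTO_028
Cyto	ZD98_CYTO_029
Cyto	ZD98_CYTO_030
Cyto	ZD98_CYTO_031
Cyto	ZD98_CYTO_032
Cyto	ZD98_CYTO_033
Cyto	ZD98_CYTO_034
Cyto	ZD98_CYTO_035
Cyto	ZD98_CYTO_036
Cyto	ZD98_CYTO_037
Cyto	ZD98_CYTO_038
Cyto	ZD98_CYTO_039
Cyto	ZD98_CYTO_040
Cyto	ZD98_CYTO_041
Cyto	ZD98_CYTO_042
Cyto	ZD98_CYTO_043
Memb	ZD98_MEMB_001
Memb	ZD98_MEMB_002
Memb	ZD98_MEMB_003
Memb	ZD98_MEMB_004
Memb	ZD98_MEMB_005
Memb	ZD98_MEMB_006
Memb	ZD98_MEMB_007
Memb	ZD98_MEMB_008
Memb	ZD98_MEMB_009
Memb	ZD98_MEMB_010
Memb	ZD98_MEMB_011
Memb	ZD98_MEMB_012
Memb	ZD98_MEMB_013
Memb	ZD98_MEMB_014
Memb	ZD98_MEMB_015
Memb	ZD98_MEMB_016
Memb	ZD98_MEMB_017
Memb	ZD98_MEMB_018
Memb	ZD98_MEMB_019
Memb	ZD98_MEMB_020
Memb	ZD98_MEMB_021
Memb	ZD98_MEMB_022
Memb	ZD98_MEMB_023
Memb	ZD98_MEMB_024
Memb	ZD98_MEMB_025
Memb	ZD98_MEMB_026
Memb	ZD98_MEMB_027
Memb	ZD98_MEMB_028
Memb	ZD98_MEMB_029
Memb	ZD98_MEMB_030
Mito	ZD98_MITO_001
Mito	ZD98_MITO_002
Mito	ZD98_MITO_003
Mito	ZD98_MITO_004
Mito	ZD98_MITO_005
Mito	ZD98_MITO_006
Mito	ZD98_MITO_007
Mito	ZD98_MITO_008
Mito	ZD98_MITO_009
Mito	ZD98_MITO_010
Mito	ZD98_MITO_011
Mito	ZD98_MITO_012
Mito	ZD98_MITO_013
Other	ZD98_OTHER_001
Other	ZD98_OTHER_002
Other	ZD98_OTHER_003
Other	ZD98_OTHER_004
Other	ZD98_OTHER_005
Other	ZD98_OTHER_006
Other	ZD98_OTHER_007
Other	ZD98_OTHER_008
Other	ZD98_OTHER_009
Other	ZD98_OTHER_010
Other	ZD98_OTHER_011
Other	ZD98_OTHER_012
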