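# ZW225 manifest TEMPLATE for the apaacsvm package.
# Two tab-separated columns: class<TAB>accession.
# The accessions below are SYNTHETIC placeholders that only reproduce the
# published per-class counts; the real UniProt accessions are not printed
# in the source describing this benchmark and must be transcribed from the
# prior publications that defined it before using the fetch helper.
Cyto	ZW225_CYTO_001
Cyto	ZW225_CYTO_002
Cyto	ZW225_CYTO_003
Cyto	ZW225_CYTO_004
Cyto	ZW225_CYTO_005
Cyto	ZW225_CYTO_006
Cyto	ZW225_CYTO_007
Cyto	ZW225_CYTO_008
Cyto	ZW225_CYTO_009
Cyto	ZW225_CYTO_010
Cyto	ZW225_CYTO_011
Cyto	ZW225_CYTO_012
Cyto	ZW225_CYTO_013
Cyto	ZW225_CYTO_014
Cyto	ZW225_CYTO_015
Cyto	ZW225_CYTO_016
Cyto	ZW225_CYTO_017
Cyto	ZW225_CYTO_018
Cyto	ZW225_CYTO_019
Cyto	ZW225_CYTO_020
Cyto	ZW225_CYTO_021
Cyto	ZW225_CYTO_022
Cyto	ZW225_CYTO_023
Cyto	ZW225_CYTO_024
Cyto	ZW225_CYTO_025
Cyto	ZW225_CYTO_026
Cyto	ZW225_CYTO_027
Cyto	ZW225_CYTO_028
Cyto	ZW225_CYTO_029
Cyto	ZW225_CYTO_030
Cyto	ZW225_CYTO_031
Cyto	ZW225_CYTO_032
Cyto	ZW225_CYTO_033
Cyto	ZW225_CYTO_034
Cyto	ZW225_CYTO_035
Cyto	ZW225_CYTO_036
Cyto	ZW225_CYTO_037
Cyto	ZW225_CYTO_038
Cyto	ZW225_CYTO_039
Cyto	ZW225_CYTO_040
Cyto	ZW225_CYTO_041
Cyto	ZW225_CYTO_042
Cyto	ZW225_CYTO_043
Cyto	ZW225_CYTO_044
Cyto	ZW225_CYTO_045
Cyto	ZW225_CYTO_046
Cyto	ZW225_CYTO_047
Cyto	ZW225_CYTO_048
Cyto	ZW225_CYTO_049
Cyto	ZW225_CYTO_050
Cyto	ZW225_CYTO_051
Cyto	ZW225_CYTO_052
Cyto	ZW225_CYTO_053
Cyto	ZW225_CYTO_054
Cyto	ZW225_CYTO_055
Cyto	ZW225_CYTO_056
Cyto	ZW225_CYTO_057
Cyto	ZW225_CYTO_058
Cyto	ZW225_CYTO_059
Cyto	ZW225_CYTO_060
Cyto	ZW225_CYTO_061
Cyto	ZW225_CYTO_062
Cyto	ZW225_CYTO_063
Cyto	ZW225_CYTO_064
Cyto	ZW225_CYTO_065
Cyto	ZW225_CYTO_066
Cyto	ZW225_CYTO_067
Cyto	ZW225_CYTO_068
Cyto	ZW225_CYTO_069
Cyto	ZW225_CYTO_070
Memb	ZW225_MEMB_001
Memb	ZW225_MEMB_002
Memb	ZW225_MEMB_003
Memb	ZW225_MEMB_004
Memb	ZW225_MEMB_005
Memb	ZW225_MEMB_006
Memb	ZW225_MEMB_007
Memb	ZW225_MEMB_008
Memb	ZW225_MEMB_009
Memb	ZW225_MEMB_010
Memb	ZW225_MEMB_011
Memb	ZW225_MEMB_012
Memb	ZW225_MEMB_013
Memb	ZW225_MEMB_014
Memb	ZW225_MEMB_015
Memb	ZW225_MEMB_016
Memb	ZW225_MEMB_017
Memb	ZW225_MEMB_018
Memb	ZW225_MEMB_019
Memb	ZW225_MEMB_020
Memb	ZW225_MEMB_021
Memb	ZW225_MEMB_022
Memb	ZW225_MEMB_023
Memb	ZW225_MEMB_024
Memb	ZW225_MEMB_025
Memb	ZW225_MEMB_026
Memb	ZW225_MEMB_027
Memb	ZW225_MEMB_028
Memb	ZW225_MEMB_029
Memb	ZW225_MEMB_030
Memb	ZW225_MEMB_031
Memb	ZW225_MEMB_032
Memb	ZW225_MEMB_033
Memb	ZW225_MEMB_034
Memb	ZW225_MEMB_035
Memb	ZW225_MEMB_036
Memb	ZW225_MEMB_037
Memb	ZW225_MEMB_038
Memb	ZW225_MEMB_039
Memb	ZW225_MEMB_040
Memb	ZW225_MEMB_041
Memb	ZW225_MEMB_042
Memb	ZW225_MEMB_043
Memb	ZW225_MEMB_044
Memb	ZW225_MEMB_045
Memb	ZW225_MEMB_046
Memb	ZW225_MEMB_047
Memb	ZW225_MEMB_048
Memb	ZW225_MEMB_049
Memb	ZW225_MEMB_050
Memb	ZW225_MEMB_051
Memb	ZW225_MEMB_052
Memb	ZW225_MEMB_053
Memb	ZW225_MEMB_054
Memb	ZW225_MEMB_055
Memb	ZW225_MEMB_056
Memb	ZW225_MEMB_057
Memb	ZW225_MEMB_058
Memb	ZW225_MEMB_059
Memb	ZW225_MEMB_060
Memb	ZW225_MEMB_061
Memb	ZW225_MEMB_062
Memb	ZW225_MEMB_063
Memb	ZW225_MEMB_064
Memb	ZW225_MEMB_065
Memb	ZW225_MEMB_066
Memb	ZW225_MEMB_067
Memb	ZW225_MEMB_068
Memb	ZW225_MEMB_069
Memb	ZW225_MEMB_070
Memb	ZW225_MEMB_071
Memb	ZW225_MEMB_072
Memb	ZW225_MEMB_073
Memb	ZW225_MEMB_074
Memb	ZW225_MEMB_075
Memb	ZW225_MEMB_076
Memb	ZW225_MEMB_077
Memb	ZW225_MEMB_078
Memb	ZW225_MEMB_079
Memb	ZW225_MEMB_080
Memb	ZW225_MEMB_081
Memb	ZW225_MEMB_082
Memb	ZW225_MEMB_083
Memb	ZW225_MEMB_084
Memb	ZW225_MEMB_085
Memb	ZW225_MEMB_086
Memb	ZW225_MEMB_087
Memb	ZW225_MEMB_088
Memb	ZW225_MEMB_089
Mito	ZW225_MITO_001
Mito	ZW225_MITO_002
Mito	ZW225_MITO_003
Mito	ZW225_MITO_004
Mito	ZW225_MITO_005
Mito	ZW225_MITO_006
Mito	ZW225_MITO_007
Mito	ZW225_MITO_008
Mito	ZW225_MITO_009
Mito	ZW225_MITO_010
Mito	ZW225_MITO_011
Mito	ZW225_MITO_012
Mito	ZW225_MITO_013
Mito	ZW225_MITO_014
Mito	ZW225_MITO_015
Mito	ZW225_MITO_016
Mito	ZW225_MITO_017
Mito	ZW225_MITO_018
Mito	ZW225_MITO_019
Mito	ZW225_MITO_020
Mito	ZW225_MITO_021
Mito	ZW225_MITO_022
Mito	ZW225_MITO_023
Mito	ZW225_MITO_024
Mito	ZW225_MITO_025
Nucl	ZW225_NUCL_001
Nucl	ZW225_NUCL_002
Nucl	ZW225_NUCL_003
Nucl	ZW225_NUCL_004
Nucl	ZW225_NUCL_005
Nucl	ZW225_NUCL_006
Nucl	ZW225_NUCL_007
Nucl	ZW225_NUCL_008
Nucl	ZW225_NUCL_009
Nucl	ZW225_NUCL_010
Nucl	ZW225_NUCL_011
Nucl	ZW225_NUCL_012
Nucl	ZW225_NUCL_013
Nucl	ZW225_NUCL_014
Nucl	ZW225_NUCL_015
Nucl	ZW225_NUCL_016
Nucl	ZW225_NUCL_017
Nucl	ZW225_NUCL_018
Nucl	ZW225_NUCL_019
Nucl	ZW225_NUCL_020
Nucl	ZW225_NUCL_021
Nucl	ZW225_NUCL_022
Nucl	ZW225_NUCL_023
Nucl	ZW225_NUCL_024
Nucl	ZW225_NUCL_025
Nucl	ZW225_NUCL_026
Nucl	ZW225_NUCL_027
Nucl	ZW225_NUCL_028
Nucl	ZW225_NUCL_029
Nucl	ZW225_NUCL_030
Nucl	ZW225_NUCL_031
Nucl	ZW225_NUCL_032
Nucl	ZW225_NUCL_033
Nucl	ZW225_NUCL_034
Nucl	ZW225_NUCL_035
Nucl	ZW225_NUCL_036
Nucl	ZW225_NUCL_037
Nucl	ZW225_NUCL_038
Nucl	ZW225_NUCL_039
Nucl	ZW225_NUCL_040
Nucl	ZW225_NUCL_041
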