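# CL317 manifest TEMPLATE for the apaacsvm package.
# Two tab-separated columns: class<TAB>accession.
# The accessions below are SYNTHETIC placeholders that only reproduce the
# published per-class counts; the real UniProt accessions are not printed
# in the source describing this benchmark and must be transcribed from the
# prior publications that defined it before using the fetch helper.
Cyto	CL317_CYTO_001
Cyto	CL317_CYTO_002
Cyto	CL317_CYTO_003
Cyto	CL317_CYTO_004
Cyto	CL317_CYTO_005
Cyto	CL317_CYTO_006
Cyto	CL317_CYTO_007
Cyto	CL317_CYTO_008
Cyto	CL317_CYTO_009
Cyto	CL317_CYTO_010
Cyto	CL317_CYTO_011
Cyto	CL317_CYTO_012
Cyto	CL317_CYTO_013
Cyto	CL317_CYTO_014
Cyto	CL317_CYTO_015
Cyto	CL317_CYTO_016
Cyto	CL317_CYTO_017
Cyto	CL317_CYTO_018
Cyto	CL317_CYTO_019
Cyto	CL317_CYTO_020
Cyto	CL317_CYTO_021
Cyto	CL317_CYTO_022
Cyto	CL317_CYTO_023
Cyto	CL317_CYTO_024
Cyto	CL317_CYTO_025
Cyto	CL317_CYTO_026
Cyto	CL317_CYTO_027
Cyto	CL317_CYTO_028
Cyto	CL317_CYTO_029
Cyto	CL317_CYTO_030
Cyto	CL317_CYTO_031
Cyto	CL317_CYTO_032
Cyto	CL317_CYTO_033
Cyto	CL317_CYTO_034
Cyto	CL317_CYTO_035
Cyto	CL317_CYTO_036
Cyto	CL317_CYTO_037
Cyto	CL317_CYTO_038
Cyto	CL317_CYTO_039
Cyto	CL317_CYTO_040
Cyto	CL317_CYTO_041
Cyto	CL317_CYTO_042
Cyto	CL317_CYTO_043
Cyto	CL317_CYTO_044
Cyto	CL317_CYTO_045
Cyto	CL317_CYTO_046
Cyto	CL317_CYTO_047
Cyto	CL317_CYTO_048
Cyto	CL317_CYTO_049
Cyto	CL317_CYTO_050
Cyto	CL317_CYTO_051
Cyto	CL317_CYTO_052
Cyto	CL317_CYTO_053
Cyto	CL317_CYTO_054
Cyto	CL317_CYTO_055
Cyto	CL317_CYTO_056
Cyto	CL317_CYTO_057
Cyto	CL317_CYTO_058
Cyto	CL317_CYTO_059
Cyto	CL317_CYTO_060
Cyto	CL317_CYTO_061
Cyto	CL317_CYTO_062
Cyto	CL317_CYTO_063
Cyto	CL317_CYTO_064
Cyto	CL317_CYTO_065
Cyto	CL317_CYTO_066
Cyto	CL317_CYTO_067
Cyto	CL317_CYTO_068
Cyto	CL317_CYTO_069
Cyto	CL317_CYTO_070
Cyto	CL317_CYTO_071
Cyto	CL317_CYTO_072
Cyto	CL317_CYTO_073
Cyto	CL317_CYTO_074
Cyto	CL317_CYTO_075
Cyto	CL317_CYTO_076
Cyto	CL317_CYTO_077
Cyto	CL317_CYTO_078
Cyto	CL317_CYTO_079
Cyto	CL317_CYTO_080
Cyto	CL317_CYTO_081
Cyto	CL317_CYTO_082
Cyto	CL317_CYTO_083
Cyto	CL317_CYTO_084
Cyto	CL317_CYTO_085
Cyto	CL317_CYTO_086
Cyto	CL317_CYTO_087
Cyto	CL317_CYTO_088
Cyto	CL317_CYTO_089
Cyto	CL317_CYTO_090
Cyto	CL317_CYTO_091
Cyto	CL317_CYTO_092
Cyto	CL317_CYTO_093
Cyto	CL317_CYTO_094
Cyto	CL317_CYTO_095
Cyto	CL317_CYTO_096
Cyto	CL317_CYTO_097
Cyto	CL317_CYTO_098
Cyto	CL317_CYTO_099
Cyto	CL317_CYTO_100
Cyto	CL317_CYTO_101
Cyto	CL317_CYTO_102
Cyto	CL317_CYTO_103
Cyto	CL317_CYTO_104
Cyto	CL317_CYTO_105
Cyto	CL317_CYTO_106
Cyto	CL317_CYTO_107
Cyto	CL317_CYTO_108
Cyto	CL317_CYTO_109
Cyto	CL317_CYTO_110
Cyto	CL317_CYTO_111
Cyto	CL317_CYTO_112
Memb	CL317_MEMB_001
Memb	CL317_MEMB_002
Memb	CL317_MEMB_003
Memb	CL317_MEMB_004
Memb	CL317_MEMB_005
Memb	CL317_MEMB_006
Memb	CL317_MEMB_007
Memb	CL317_MEMB_008
Memb	CL317_MEMB_009
Memb	CL317_MEMB_010
Memb	CL317_MEMB_011
Memb	CL317_MEMB_012
Memb	CL317_MEMB_013
Memb	CL317_MEMB_014
Memb	CL317_MEMB_015
Memb	CL317_MEMB_016
Memb	CL317_MEMB_017
Memb	CL317_MEMB_018
Memb	CL317_MEMB_019
Memb	CL317_MEMB_020
Memb	CL317_MEMB_021
Memb	CL317_MEMB_022
Memb	CL317_MEMB_023
Memb	CL317_MEMB_024
Memb	CL317_MEMB_025
Memb	CL317_MEMB_026
Memb	CL317_MEMB_027
Memb	CL317_MEMB_028
Memb	CL317_MEMB_029
Memb	CL317_MEMB_030
Memb	CL317_MEMB_031
Memb	CL317_MEMB_032
Memb	CL317_MEMB_033
Memb	CL317_MEMB_034
Memb	CL317_MEMB_035
Memb	CL317_MEMB_036
Memb	CL317_MEMB_037
Memb	CL317_MEMB_038
Memb	CL317_MEMB_039
Memb	CL317_MEMB_040
Memb	CL317_MEMB_041
Memb	CL317_MEMB_042
Memb	CL317_MEMB_043
Memb	CL317_MEMB_044
Memb	CL317_MEMB_045
Memb	CL317_MEMB_046
Memb	CL317_MEMB_047
Memb	CL317_MEMB_048
Memb	CL317_MEMB_049
Memb	CL317_MEMB_050
Memb	CL317_MEMB_051
Memb	CL317_MEMB_052
Memb	CL317_MEMB_053
Memb	CL317_MEMB_054
Memb	CL317_MEMB_055
Nucl	CL317_NUCL_001
Nucl	CL317_NUCL_002
Nucl	CL317_NUCL_003
Nucl	CL317_NUCL_004
Nucl	CL317_NUCL_005
Nucl	CL317_NUCL_006
Nucl	CL317_NUCL_007
Nucl	CL317_NUCL_008
Nucl	CL317_NUCL_009
Nucl	CL317_NUCL_010
Nucl	CL317_NUCL_011
Nucl	CL317_NUCL_012
Nucl	CL317_NUCL_013
Nucl	CL317_NUCL_014
Nucl	CL317_NUCL_015
Nucl	CL317_NUCL_016
Nucl	CL317_NUCL_017
Nucl	CL317_NUCL_018
Nucl	CL317_NUCL_019
Nucl	CL317_NUCL_020
Nucl	CL317_NUCL_021
Nucl	CL317_NUCL_022
Nucl	CL317_NUCL_023
Nucl	CL317_NUCL_024
Nucl	CL317_NUCL_025
Nucl	CL317_NUCL_026
Nucl	CL317_NUCL_027
Nucl	CL317_NUCL_028
Nucl	CL317_NUCL_029
Nucl	CL317_NUCL_030
Nucl	CL317_NUCL_031
Nucl	CL317_NUCL_032
Nucl	CL317_NUCL_033
Nucl	CL317_NUCL_034
Nucl	CL317_NUCL_035
Nucl	CL317_NUCL_036
Nucl	CL317_NUCL_037
Nucl	CL317_NUCL_038
Nucl	CL317_NUCL_039
Nucl	CL317_NUCL_040
Nucl	CL317_NUCL_041
Nucl	CL317_NUCL_042
Nucl	CL317_NUCL_043
Nucl	CL317_NUCL_044
Nucl	CL317_NUCL_045
Nucl	CL317_NUCL_046
Nucl	CL317_NUCL_047
Nucl	CL317_NUCL_048
Nucl	CL317_NUCL_049
Nucl	CL317_NUCL_050
Nucl	CL317_NUCL_051
Nucl	CL317_NUCL_052
Endo	CL317_ENDO_001
Endo	CL317_ENDO_002
Endo	CL317_ENDO_003
Endo	CL317_ENDO_004
Endo	CL317_ENDO_005
Endo	CL317_ENDO_006
Endo	CL317_ENDO_007
Endo	CL317_ENDO_008
Endo	CL317_ENDO_009
Endo	CL317_ENDO_010
Endo	CL317_ENDO_011
Endo	CL317_ENDO_012
Endo	CL317_ENDO_013
Endo	CL317_ENDO_014
Endo	CL317_ENDO_015
Endo	CL317_ENDO_016
Endo	CL317_ENDO_017
Endo	CL317_ENDO_018
Endo	CL317_ENDO_019
Endo	CL317_ENDO_020
Endo	CL317_ENDO_021
Endo	CL317_ENDO_022
Endo	CL317_ENDO_023
Endo	CL317_ENDO_024
Endo	CL317_ENDO_025
Endo	CL317_ENDO_026
Endo	CL317_ENDO_027
Endo	CL317_ENDO_028
Endo	CL317_ENDO_029
Endo	CL317_ENDO_030
Endo	CL317_ENDO_031
Endo	CL317_ENDO_032
Endo	CL317_ENDO_033
Endo	CL317_ENDO_034
Endo	CL317_ENDO_035
Endo	CL317_ENDO_036
Endo	CL317_ENDO_037
Endo	CL317_ENDO_038
Endo	CL317_ENDO_039
Endo	CL317_ENDO_040
Endo	CL317_ENDO_041
Endo	CL317_ENDO_042
Endo	CL317_ENDO_043
Endo	CL317_ENDO_044
Endo	CL317_ENDO_045
Endo	CL317_ENDO_046
Endo	CL317_ENDO_047
Mito	CL317_MITO_001
Mito	CL317_MITO_002
Mito	CL317_MITO_003
Mito	CL317_MITO_004
Mito	CL317_MITO_005
Mito	CL317_MITO_006
Mito	CL317_MITO_007
Mito	CL317_MITO_008
Mito	CL317_MITO_009
Mito	CL317_MITO_010
Mito	CL317_MITO_011
Mito	CL317_MITO_012
Mito	CL317_MITO_013
Mito	CL317_MITO_014
Mito	CL317_MITO_015
Mito	CL317_MITO_016
Mito	CL317_MITO_017
Mito	CL317_MITO_018
Mito	CL317_MITO_019
Mito	CL317_MITO_020
Mito	CL317_MITO_021
Mito	CL317_MITO_022
Mito	CL317_MITO_023
Mito	CL317_MITO_024
Mito	CL317_MITO_025
Mito	CL317_MITO_026
Mito	CL317_MITO_027
Mito	CL317_MITO_028
Mito	CL317_MITO_029
Mito	CL317_MITO_030
Mito	CL317_MITO_031
Mito	CL317_MITO_032
Mito	CL317_MITO_033
Mito	CL317_MITO_034
Secr	CL317_SECR_001
Secr	CL317_SECR_002
Secr	CL317_SECR_003
Secr	CL317_SECR_004
Secr	CL317_SECR_005
Secr	CL317_SECR_006
Secr	CL317_SECR_007
Secr	CL317_SECR_008
Secr	CL317_SECR_009
Secr	CL317_SECR_010
Secr	CL317_SECR_011
Secr	CL317_SECR_012
Secr	CL317_SECR_013
Secr	CL317_SECR_014
Secr	CL317_SECR_015
Secr	CL317_SECR_016
Secr	CL317_SECR_017
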