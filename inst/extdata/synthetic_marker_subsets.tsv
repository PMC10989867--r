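set_name	marker_id
undin28	cog0001
undin28	cog0002
undin28	cog0003
undin28	cog0004
undin28	cog0005
undin28	cog0006
undin28	cog0007
undin28	cog0008
undin28	cog0009
undin28	cog0010
undin28	cog0011
undin28	cog0012
undin28	cog0013
undin28	cog0014
undin28	cog0015
undin28	cog0016
undin28	cog0017
undin28	cog0018
undin28	cog0019
undin28	cog0020
undin28	cog0021
undin28	cog0022
undin28	cog0023
undin28	cog0024
undin28	cog0025
undin28	cog0026
undin28	cog0027
undin28	cog0028
undin56	cog0001
undin56	cog0002
undin56	cog0003
undin56	cog0004
undin56	cog0005
undin56	cog0006
undin56	cog0007
undin56	cog0008
undin56	cog0009
undin56	cog0010
undin56	cog0011
undin56	cog0012
undin56	cog0013
undin56	cog0014
undin56	cog0015
undin56	cog0016
undin56	cog0017
undin56	cog0018
undin56	cog0019
undin56	cog0020
undin56	cog0021
undin56	cog0022
undin56	cog0023
undin56	cog0024
undin56	cog0025
undin56	cog0026
undin56	cog0027
undin56	cog0028
undin56	cog0029
undin56	cog0030
undin56	cog0031
undin56	cog0032
undin56	cog0033
undin56	cog0034
undin56	cog0035
undin56	cog0036
undin56	cog0037
undin56	cog0038
undin56	cog0039
undin56	cog0040
undin56	cog0041
undin56	cog0042
undin56	cog0043
undin56	cog0044
undin56	cog0045
undin56	cog0046
undin56	cog0047
undin56	cog0048
undin56	cog0049
undin56	cog0050
undin56	cog0051
undin56	cog0052
undin56	cog0053
undin56	cog0054
undin56	cog0055
undin56	cog0056
tacka60	cog0001
tacka60	cog0002
tacka60	cog0003
tacka60	cog0004
tacka60	cog0005
tacka60	cog0006
tacka60	cog0007
tacka60	cog0008
tacka60	cog0009
tacka60	cog0010
tacka60	cog0011
tacka60	cog0012
tacka60	cog0013
tacka60	cog0014
tacka60	cog0015
tacka60	cog0016
tacka60	cog0017
tacka60	cog0018
tacka60	cog0019
tacka60	cog0057
tacka60	cog0058
tacka60	cog0059
tacka60	cog0060
tacka60	cog0061
tacka60	cog0062
tacka60	cog0063
tacka60	cog0064
tacka60	cog0065
tacka60	cog0066
tacka60	cog0067
tacka60	cog0068
tacka60	cog0069
tacka60	cog0070
tacka60	cog0071
tacka60	cog0072
tacka60	cog0073
tacka60	cog0074
tacka60	cog0075
tacka60	cog0076
tacka60	cog0077
tacka60	cog0078
tacka60	cog0079
tacka60	cog0080
tacka60	cog0081
tacka60	cog0082
tacka60	cog0083
tacka60	cog0084
tacka60	cog0085
tacka60	cog0086
tacka60	cog0087
tacka60	cog0088
tacka60	cog0089
tacka60	cog0090
tacka60	cog0091
tacka60	cog0092
tacka60	cog0093
tacka60	cog0094
tacka60	ascog001
tacka60	ascog002
tacka60	ascog003
tacka120	cog0001
tacka120	cog0002
tacka120	cog0003
tacka120	cog0004
tacka120	cog0005
tacka120	cog0006
tacka120	cog0007
tacka120	cog0008
tacka120	cog0009
tacka120	cog0010
tacka120	cog0011
tacka120	cog0012
tacka120	cog0013
tacka120	cog0014
tacka120	cog0015
tacka120	cog0016
tacka120	cog0017
tacka120	cog0018
tacka120	cog0019
tacka120	cog0057
tacka120	cog0058
tacka120	cog0059
tacka120	cog0060
tacka120	cog0061
tacka120	cog0062
tacka120	cog0063
tacka120	cog0064
tacka120	cog0065
tacka120	cog0066
tacka120	cog0067
tacka120	cog0068
tacka120	cog0069
tacka120	cog0070
tacka120	cog0071
tacka120	cog0072
tacka120	cog0073
tacka120	cog0074
tacka120	cog0075
tacka120	cog0076
tacka120	cog0077
tacka120	cog0078
tacka120	cog0079
tacka120	cog0080
tacka120	cog0081
tacka120	cog0082
tacka120	cog0083
tacka120	cog0084
tacka120	cog0085
tacka120	cog0086
tacka120	cog0087
tacka120	cog0088
tacka120	cog0089
tacka120	cog0090
tacka120	cog0091
tacka120	cog0092
tacka120	cog0093
tacka120	cog0094
tacka120	ascog001
tacka120	ascog002
tacka120	ascog003
tacka120	cog0095
tacka120	cog0096
tacka120	cog0097
tacka120	cog0098
tacka120	cog0099
tacka120	cog0100
tacka120	cog0101
tacka120	cog0102
tacka120	cog0103
tacka120	cog0104
tacka120	cog0105
tacka120	cog0106
tacka120	cog0107
tacka120	cog0108
tacka120	cog0109
tacka120	cog0110
tacka120	cog0111
tacka120	cog0112
tacka120	cog0113
tacka120	cog0114
tacka120	cog0115
tacka120	cog0116
tacka120	cog0117
tacka120	cog0118
tacka120	arcog00001
tacka120	arcog00002
tacka120	arcog00003
tacka120	arcog00004
tacka120	arcog00005
tacka120	arcog00006
tacka120	arcog00007
tacka120	arcog00008
tacka120	arcog00009
tacka120	arcog00010
tacka120	arcog00011
tacka120	arcog00012
tacka120	arcog00013
tacka120	arcog00014
tacka120	arcog00015
tacka120	arcog00016
tacka120	arcog00017
tacka120	arcog00018
tacka120	arcog00019
tacka120	arcog00020
tacka120	arcog00021
tacka120	arcog00022
tacka120	arcog00023
tacka120	arcog00024
tacka120	arcog00025
tacka120	arcog00026
tacka120	arcog00027
tacka120	arcog00028
tacka120	arcog00029
tacka120	arcog00030
tacka120	arcog00031
tacka120	arcog00032
tacka120	arcog00033
tacka120	ascog004
tacka120	ascog005
tacka120	ascog006
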