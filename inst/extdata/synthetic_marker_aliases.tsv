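accession	canonical
tigr00001	cog0020
tigr00002	cog0021
tigr00003	cog0022
tigr00004	cog0023
tigr00005	cog0024
tigr00006	cog0025
tigr00007	cog0026
tigr00008	cog0027
tigr00009	cog0028
tigr00010	cog0029
tigr00011	cog0030
tigr00012	cog0031
tigr00013	cog0032
tigr00014	cog0033
tigr00015	cog0034
tigr00016	cog0035
tigr00017	cog0036
tigr00018	cog0037
tigr00019	cog0038
tigr00020	cog0039
tigr00021	cog0040
tigr00022	cog0041
tigr00023	cog0042
tigr00024	cog0043
tigr00025	cog0044
tigr00026	cog0045
tigr00027	cog0046
tigr00028	cog0047
tigr00029	cog0048
tigr00030	cog0049
tigr00031	cog0050
tigr00032	cog0051
tigr00033	cog0052
tigr00034	cog0053
tigr00035	cog0054
tigr00036	cog0055
tigr00037	cog0056
tigr00038	cog0057
tigr00039	cog0058
tigr00040	cog0059
tigr00041	cog0060
tigr00042	cog0061
tigr00043	cog0062
tigr00044	cog0063
tigr00045	cog0064
tigr00046	cog0065
tigr00047	cog0066
tigr00048	cog0067
tigr00049	cog0068
tigr00050	cog0069
tigr00051	cog0070
tigr00052	cog0071
tigr00053	cog0072
tigr00054	cog0073
tigr00055	cog0074
tigr00056	cog0075
tigr00057	cog0076
tigr00058	cog0077
tigr00059	cog0078
tigr00060	cog0079
tigr00061	cog0080
tigr00062	cog0081
tigr00063	cog0082
tigr00064	cog0083
tigr00065	cog0084
tigr00066	cog0085
tigr00067	cog0086
tigr00068	cog0087
tigr00069	cog0088
tigr00070	cog0089
tigr00071	cog0090
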