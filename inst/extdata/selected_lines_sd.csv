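line,set,sd_nap,sd_ap
VML002,top20,4.56,6.32
VML153,top20,4.99,6.78
VML137,top20,5.51,7.86
VML036,top20,4.77,7.63
VML121,top20,5.61,7.83
VML119,top20,4.62,7.31
VML030,top20,5.45,8.23
VML133,top20,4.72,7.55
VML130,top20,4.35,6.95
VML174,top20,5.24,7.94
VML001,top20,4.47,7.81
VML165,top20,5.56,8.76
VML041,top20,5.55,8.26
VML179,top20,5.10,7.74
VML009,top20,5.15,9.14
VML087,top20,4.78,8.27
VML004,top20,5.18,9.35
VML042,top20,5.15,8.58
VML113,top20,5.03,8.95
VML046,top20,5.12,9.32
VML125,bottom5,4.25,8.40
VML129,bottom5,3.57,8.54
VML067,bottom5,4.10,9.01
VML086,bottom5,3.46,8.14
VML051,bottom5,3.60,8.08
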