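compound	cv	mav_freeze_thaw	mav_minus20	mav_fridge	mav_room
15N;2-13C-glycine	0.580	0.975	1.732	6.999	1.855
2H4-alanine	0.161	0.371	0.070	0.171	0.188
2H3-leucine	0.166	0.411	0.037	0.158	0.265
2H3-methionine	0.775	3.388	0.188	0.607	0.359
13C6-phenylalanine	0.149	0.374	0.050	0.142	0.204
13C6-tyrosine	0.150	0.349	0.043	0.098	0.206
2H3-aspartate	0.160	0.349	0.137	0.110	0.155
2H3-glutamate	0.126	0.247	0.099	0.110	0.074
2H2-ornithine	0.183	0.540	0.014	0.108	0.168
2H2-citrulline	0.134	0.231	0.070	0.131	0.038
2H4;13C-arginine	0.163	0.380	0.105	0.190	0.170
2H8-valine	0.155	0.377	0.042	0.124	0.222
2H9-carnitine	0.202	0.580	0.072	0.179	0.162
2H3-acetylcarnitine	1.058	432.707	689.785	0.567	0.999
2H3-propionylcarnitine	0.194	0.384	0.038	0.225	0.161
2H3-butyrylcarnitine	2.914	42.155	0.164	92.851	0.277
2H9-isovalerylcarnitine	0.217	0.519	0.103	0.215	0.173
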