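id,parent_id,x0,y0,z0,x1,y1,z1,diameter_m
1,,0,0,0,0,0,-0.12,0.018
2,1,0,0,-0.12,0.05,0,-0.17,0.0126
3,1,0,0,-0.12,-0.05,0,-0.17,0.0126
4,2,0.05,0,-0.17,0.09,0.01,-0.2,0.0088
5,2,0.05,0,-0.17,0.04,-0.02,-0.21,0.0088
6,3,-0.05,0,-0.17,-0.09,0.01,-0.2,0.0088
7,3,-0.05,0,-0.17,-0.04,-0.02,-0.21,0.0088
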