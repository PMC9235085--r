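case,cause,cosine,mean_error_mm
1,deformity,0.96,0.43
2,tumor,0.94,0.61
3,tumor,0.95,0.45
4,fracture,0.97,0.44
5,deformity,0.98,0.41
6,deformity,0.98,0.34
7,fracture,0.96,0.42
8,fracture,0.96,0.44
9,deformity,0.98,0.44
10,deformity,0.96,0.46
11,tumor,0.97,0.44
12,tumor,0.96,0.44
13,tumor,0.95,0.63
14,tumor,0.96,0.56
15,tumor,0.94,0.62
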