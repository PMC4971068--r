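segment	assembly_bp	cds_bp	ncds_bp
1	3210343	2836815	373528
2	3217969	2843091	374878
3	3239714	2882289	357425
4	3116424	2757582	358842
5	2544604	2221023	323581
6	2402354	2106546	295808
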