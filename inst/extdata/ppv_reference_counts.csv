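pi,reached_euploid,reached_no_euploid,not_reached_euploid,not_reached_no_euploid
0.7,317,57,334,756
0.8,217,31,434,782
0.9,135,15,516,798
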