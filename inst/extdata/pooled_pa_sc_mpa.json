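{"variables":["PA","SC","MPA"],"r":[[1,0.213,-0.184],[0.213,1,-0.449],[-0.184,-0.449,1]],"n_effective":11386,"cell_k":[]}
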