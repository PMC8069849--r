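from,to,label,p,theta
black_spruce,bog,thermokarst,1,0
bog,shrubland,permafrost_peat_aggradation,1,0
shrubland,black_spruce,aggradation_tree_regeneration,1,0
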