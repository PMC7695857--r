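segment_id,bp_index,strand,source
1,100,0,direct
1,103,0,direct
1,105,1,indirect
1,500,0,indirect
1,5000,0,direct
1,5003,1,direct
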