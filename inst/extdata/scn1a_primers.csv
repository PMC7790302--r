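name,left_exon,left_offset,left_len,left_junction,right_exon,right_offset,right_len,right_junction
amplicon1,ex20,245,23,,ex21,8,20,
amplicon2,ex20,257,23,ex20N,ex20N,56,24,ex21
amplicon3,ex19,118,21,,ex20,34,21,
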