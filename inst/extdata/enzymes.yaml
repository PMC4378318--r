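# Example enzyme definitions for load_enzymes(); cut_offset is the
# distance in bases from the motif start to the top-strand cut point.
- name: Sau96I
  motif: GGNCC
  cut_offset: 1
- name: DdeI
  motif: CTNAG
  cut_offset: 1
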