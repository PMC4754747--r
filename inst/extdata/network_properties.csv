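system,chain,n_nodes,n_edges,average_degree,average_clustering,degree_residue_36
hBBCK,A,367,953,5.193,0.212,4
hBBCK,B,363,872,4.804,0.192,2
BP36L,A,371,996,5.369,0.220,6
BP36L,B,367,953,5.193,0.223,6
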