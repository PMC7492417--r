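quantity	value
n_arrays_whole_set	14591
n_monomers_whole_set	51024
n_arrays_clustered	9902
n_arrays_unclustered	4689
n_clusters	393
n_arrays_2_3_monomers	8224
n_arrays_ge5_monomers_whole_set	2282
genome_size_bp	559000000
longest_array_monomers	29.3
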