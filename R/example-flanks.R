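# Synthetic 120-bp flanks for example_construct(), generated once and
# screened so neither 12-bp anchor recurs within 2 mismatches anywhere in
# the construct or its reverse complement (including partial-overlap
# windows at the random-sequence boundaries).
.barquant_example_flanks <- list(
  left = paste0(
    "GCGGGTCGGCCATCTCCGGTCCCCTCGAAACATGGAGGTCGGTGATACAATAGAGAACGT",
    "GGTACCGTCCTAATCCTTGCTATCCTATATAGACTCGGGAACATTATCGATTACCACATC"),
  right = paste0(
    "GTCGAAGGTGTTAGCATAGACCTCTGGGAAAGCGGGGGTTGAACGACGTCCTAACGTAGG",
    "CGTTCATCGACCAAACAGTTCTAAACCAGCACAGGCAATAATAATGCACTAGCACCAGAG")
)
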