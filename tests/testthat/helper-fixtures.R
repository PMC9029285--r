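random_oligomer <- function(len, name = "rand") {
  oligomer(paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = ""), name)
}

# Two-strand schematic with exactly 3 complementary opposing pairs at
# r = 0, of which only 2 adjacent: strand 1 is all A, so an opposing T
# pairs and anything else does not. Reversed strand 2 reads TTCCTCCC.
schematic_pair <- function() {
  list(s1 = oligomer(strrep("A", 11), "s1"),
       s2 = oligomer("CCCTCCTT", "s2"))
}

# Expect no bonds shared between two frames' worth of base occupancy
expect_one_bond_per_base <- function(frame) {
  idx <- as.vector(frame$pairs)
  expect_true(!anyDuplicated(idx))
}
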