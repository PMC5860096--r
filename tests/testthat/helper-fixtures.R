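# Shared fixtures, built in code. Seeds are fixed so every run sees the
# same objects.

uniform_bg <- estimate_background("ACGTACGT", order = 0, pseudocount = 0)

# a mildly skewed order-0 background
skew_bg <- estimate_background(strrep("AATGCAATT", 30), order = 0,
                               pseudocount = 1)

# an order-1 background fitted to a fixed sample with CpG-like structure
bg_order1 <- local({
  set.seed(101)
  base <- sample_sequences(uniform_bg, 1, 20000, seed = 101)
  # enrich CG dinucleotides to give the chain real first-order structure
  seq1 <- gsub("GA", "CG", base)
  estimate_background(seq1, order = 1, pseudocount = 1)
})

fix <- fixture_motifs(0.01)

random_pfm <- function(M, seed) {
  set.seed(seed)
  m <- matrix(stats::rgamma(4 * M, shape = 1) + 0.05, nrow = 4)
  m <- sweep(m, 2, colSums(m), "/")
  motifclump:::new_pfm(m, name = paste0("rand", M, "_", seed))
}

rc_word <- motifclump:::reverse_complement
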