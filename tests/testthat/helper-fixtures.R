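# Shared fixtures, built in code.

wag <- bdmshift::subst_model("WAG")
jtt <- bdmshift::subst_model("JTT")
g2 <- bdmshift::discretize_gamma(1.1990, 2)
g1 <- bdmshift::discretize_gamma(1, 1L)

# small 4-taxon tree used across likelihood/ancestral oracles
quartet <- function() read_newick("((A:0.1,B:0.25):0.07,(C:0.18,D:0.3):0.12);")

sim_quartet_aln <- function(L = 40L, seed = 5) {
  simulate_alignment(sim_config(phy = quartet(), L = L, seed = seed))$alignment
}

# brute-force site likelihood on the quartet topology ((A,B)u,(C,D)v)r by
# exhaustive enumeration of the 20^3 internal-state assignments
brute_quartet_site <- function(codes, bls, model, rates) {
  tot <- 0
  for (c in seq_len(rates$k)) {
    P <- lapply(bls, function(t) transition_matrix(model, t, rates$rates[c]))
    s <- 0
    for (ru in 1:20) for (rv in 1:20) for (rr in 1:20) {
      s <- s + model$pi[rr] * P[[3]][rr, ru] * P[[6]][rr, rv] *
        P[[1]][ru, codes[1]] * P[[2]][ru, codes[2]] *
        P[[4]][rv, codes[3]] * P[[5]][rv, codes[4]]
    }
    tot <- tot + rates$weights[c] * s
  }
  tot
}

encode_rows <- function(aln, order) {
  t(sapply(order, function(n) {
    match(strsplit(aln$seqs[match(n, aln$names)], "")[[1]],
          get("AA20", asNamespace("bdmshift")))
  }))
}

quartet_bls <- c(0.1, 0.25, 0.07, 0.18, 0.3, 0.12)  # A, B, u, C, D, v

tmp_fasta <- function(seqs) {
  path <- withr::local_tempfile(fileext = ".fasta", .local_envir = parent.frame())
  writeLines(as.vector(rbind(paste0(">", names(seqs)), seqs)), path)
  path
}
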