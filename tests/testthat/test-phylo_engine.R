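test_that("degenerate likelihoods have their closed forms", {
  # two leaves at total distance 0 with identical sequences: lnL = sum log pi
  phy <- read_newick("(A:0,B:0);")
  aln <- protein_alignment(c(A = "ACDEF", B = "ACDEF"))
  ll <- site_log_likelihood(aln, phy, wag, g1)
  codes <- match(strsplit("ACDEF", "")[[1]], rownames(wag$S))
  expect_equal(ll$lnL, sum(log(wag$pi[codes])), tolerance = 1e-10)
  expect_equal(ll$site_lnL, log(wag$pi[codes]), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("pruning equals brute-force enumeration on a quartet", {
  aln <- sim_quartet_aln(L = 12L, seed = 5)
  for (rates in list(g1, g2)) {
    ll <- site_log_likelihood(aln, quartet(), wag, rates)
    enc <- encode_rows(aln, c("A", "B", "C", "D"))
    oracle <- log(vapply(seq_len(aln$L), function(s) {
      brute_quartet_site(enc[, s], quartet_bls, wag, rates)
    }, numeric(1)))
    expect_equal(ll$site_lnL, oracle, tolerance = 1e-10)
  }
})

test_that("pruning equals brute-force enumeration on 5-taxon trees", {
  # caterpillar (((A,B),C),D),E with 4 internal nodes incl. root
  nwk <- "((((A:0.12,B:0.21):0.08,C:0.3):0.11,D:0.2):0.09,E:0.27);"
  phy <- read_newick(nwk)
  sim <- simulate_alignment(sim_config(phy = phy, L = 8L, seed = 9, k = 1L,
                                       alpha = 1))
  aln <- sim$alignment
  ll <- site_log_likelihood(aln, phy, wag, g1)
  # brute force: enumerate all 20^4 internal assignments
  enc <- encode_rows(aln, c("A", "B", "C", "D", "E"))
  P <- lapply(c(0.12, 0.21, 0.08, 0.3, 0.11, 0.2, 0.09, 0.27),
              function(t) transition_matrix(wag, t))
  # internal nodes: u=(A,B), v=(u,C), w=(v,D), r=(w,E)
  oracle <- vapply(seq_len(aln$L), function(s) {
    tot <- 0
    for (u in 1:20) for (v in 1:20) for (w in 1:20) for (r in 1:20) {
      tot <- tot + wag$pi[r] * P[[7]][r, w] * P[[8]][r, enc[5, s]] *
        P[[5]][w, v] * P[[6]][w, enc[4, s]] *
        P[[3]][v, u] * P[[4]][v, enc[3, s]] *
        P[[1]][u, enc[1, s]] * P[[2]][u, enc[2, s]]
    }
    log(tot)
  }, numeric(1))
  expect_equal(ll$site_lnL, oracle, tolerance = 1e-10)
})

test_that("likelihood is invariant to root placement (pulley principle)", {
  nwk <- "((((A:0.12,B:0.21):0.08,C:0.3):0.11,D:0.2):0.09,E:0.27);"
  phy <- read_newick(nwk)
  sim <- simulate_alignment(sim_config(phy = phy, L = 50L, seed = 10))
  base <- site_log_likelihood(sim$alignment, phy, wag, g2)$lnL
  un <- ape::unroot(phy)
  for (og in c("A", "C", "E")) {
    re <- assign_node_ids(ape::root(un, outgroup = og, resolve.root = TRUE))
    expect_equal(site_log_likelihood(sim$alignment, re, wag, g2)$lnL, base,
                 tolerance = 1e-8)
  }
})

test_that("total lnL matches phangorn on gamma-mixture data", {
  skip_if_not_installed("phangorn")
  phy <- quartet()
  aln <- sim_quartet_aln(L = 80L, seed = 21)
  mat <- t(sapply(aln$seqs, function(s) strsplit(s, "")[[1]]))
  rownames(mat) <- aln$names
  pd <- phangorn::phyDat(mat, type = "AA")
  fit <- phangorn::pml(phy, pd, model = "WAG", k = 2, shape = 1.1990)
  expect_equal(site_log_likelihood(aln, phy, wag, g2)$lnL, fit$logLik,
               tolerance = 1e-5)
})

test_that("scaling leaves likelihoods exact for many-sequence alignments", {
  # 64 identical-length sequences: per-site likelihoods stay finite and the
  # alignment of 2 copies of the data gives exactly doubled lnL
  tr <- balanced_tree(64, depth = 2)
  sim <- simulate_alignment(sim_config(phy = tr, L = 30L, seed = 4))
  ll <- site_log_likelihood(sim$alignment, tr, wag, g2)
  expect_true(all(is.finite(ll$site_lnL)))
  double <- protein_alignment(setNames(
    paste0(sim$alignment$seqs, sim$alignment$seqs), sim$alignment$names))
  expect_equal(site_log_likelihood(double, tr, wag, g2)$lnL, 2 * ll$lnL,
               tolerance = 1e-8)
})

test_that("branch-length optimization is monotone and finds zero branches", {
  phy <- quartet()
  sim <- simulate_alignment(sim_config(phy = phy, L = 150L, seed = 3))
  start <- phy
  start$edge.length <- rep(0.4, nrow(start$edge))
  lnL0 <- site_log_likelihood(sim$alignment, start, wag, g2)$lnL
  opt <- optimize_branch_lengths(sim$alignment, start, wag, g2)
  expect_gte(opt$lnL, lnL0)
  expect_true(opt$converged)

  # identical flanking sequences force a zero branch
  aln2 <- protein_alignment(c(A = "MKVLW", B = "MKVLW", C = "GASTR", D = "GASTQ"))
  opt2 <- optimize_branch_lengths(aln2, phy, wag, g1)
  ab_edge <- which(opt2$tree$edge[, 2] == match("B", opt2$tree$tip.label))
  expect_lte(opt2$tree$edge.length[ab_edge], 1e-6)
})

test_that("branch lengths are recovered from long simulated alignments", {
  nwk <- "(((a:0.1,b:0.2):0.15,(c:0.12,d:0.3):0.08):0.2,e:0.25,f:0.1);"
  phy <- assign_node_ids(ape::unroot(read_newick(nwk)))
  sim <- simulate_alignment(sim_config(phy = phy, L = 2000L, seed = 11))
  start <- phy
  start$edge.length <- rep(0.1, nrow(start$edge))
  opt <- optimize_branch_lengths(sim$alignment, start, wag, g2)
  truth <- phy$edge.length
  est <- opt$tree$edge.length
  idx <- truth >= 0.05
  expect_true(all(abs(est[idx] - truth[idx]) / truth[idx] < 0.15))
})

test_that("NJ recovers additive trees exactly and ignores input order", {
  # distances constructed from a known tree metric are recovered exactly
  nwk <- "((a:0.11,b:0.23):0.07,(c:0.19,d:0.31):0.05);"
  phy <- ape::unroot(read_newick(nwk))
  D <- ape::cophenetic.phylo(phy)
  est <- nj_tree(D)
  expect_equal(ape::dist.topo(ape::unroot(est), phy), 0, ignore_attr = TRUE)
  ref <- ape::cophenetic.phylo(est)[rownames(D), colnames(D)]
  expect_equal(ref, D, tolerance = 1e-9)

  perm <- c("c", "a", "d", "b")
  est2 <- nj_tree(D[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(est2), ape::unroot(est)), 0,
               ignore_attr = TRUE)

  # agreement with the reference NJ implementation on a noisy matrix
  set.seed(8)
  noisy <- D + matrix(runif(16, 0, 0.02), 4)
  noisy <- (noisy + t(noisy)) / 2; diag(noisy) <- 0
  expect_equal(ape::dist.topo(ape::unroot(nj_tree(noisy)),
                              ape::unroot(ape::nj(noisy))), 0,
               ignore_attr = TRUE)
  expect_error(nj_tree(D[1:2, 1:2]), "at least 3")
  # ultrametric 3-taxon star resolves with nonnegative lengths
  D3 <- matrix(0.4, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(D3) <- 0
  star <- nj_tree(D3)
  expect_true(all(star$edge.length >= 0))
})

test_that("ML pairwise distances behave like distances", {
  aln <- protein_alignment(c(A = "MKVLWAAL", B = "MKVLWAAL", C = "GASTRQPN"))
  D <- protein_distance(aln, wag, g1)
  expect_equal(D["A", "B"], 0)
  expect_true(isSymmetric(D))
  # all-different pair: model correction inflates beyond the p-distance
  expect_gte(D["A", "C"], 1)
  # recovery: two sequences simulated at true distance 0.5
  two <- read_newick("(x:0.25,y:0.25);")
  sim <- simulate_alignment(sim_config(phy = two, L = 5000L, seed = 13))
  Dx <- protein_distance(sim$alignment, wag, g2)
  expect_lt(abs(Dx["x", "y"] - 0.5) / 0.5, 0.10)
})

test_that("bootstrap supports are high on clean well-separated data", {
  phy <- balanced_tree(8, depth = 1)
  phy$edge.length <- rep(0.3, nrow(phy$edge))
  sim <- simulate_alignment(sim_config(phy = phy, L = 1000L, seed = 17))
  bs <- bootstrap_support(sim$alignment, wag, g2, B = 50L, seed = 17)
  # the NJ tree should match the generating topology...
  expect_equal(ape::dist.topo(ape::unroot(bs$tree), ape::unroot(phy)), 0,
               ignore_attr = TRUE)
  # ...and every true bipartition should be strongly supported
  expect_true(all(bs$support$support_pct >= 90))
})
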