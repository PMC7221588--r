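test_that("the default BDM derivation is a symmetric difference measure", {
  bdm <- derive_bdm()
  expect_true(all(diag(unclass(bdm)) == 0))
  expect_true(all(bdm == t(bdm)))
  expect_true(all(bdm >= 0))
  # hand lookup: s(D,D)=6, s(E,E)=5, s(D,E)=2 -> 6 + 5 - 4 = 7
  expect_equal(unclass(bdm)["D", "E"], 7)
  expect_equal(unclass(bdm)["L", "L"], 0)
})

test_that("neighbor branches follow the internal-branch rules", {
  # fully internal focal branch, no adjacent leaves -> 4 neighbors
  nwk <- paste0("(((a:1,b:1):1,(c:1,d:1):1):1,((e:1,f:1):1,(g:1,h:1):1):1,",
                "((i:1,j:1):1,(k:1,l:1):1):1);")
  phy <- read_newick(nwk)
  tab <- tree_branch_table(phy)
  # branch from the root to the (abcd) ancestor: endpoints internal, all 4
  # incident branches internal
  ab <- ape::getMRCA(phy, c("a", "b"))
  abcd <- ape::getMRCA(phy, c("a", "d"))
  root <- ape::Ntip(phy) + 1L
  focal <- paste0(phy$node.id[root], "-", phy$node.id[abcd])
  nb <- neighbor_branches(phy, focal)
  expect_equal(nrow(nb), 4L)
  expect_false(focal %in% nb$branch)

  # focal with one adjacent cherry loses the leaf-incident branches
  phy2 <- read_newick("(((a:1,b:1):1,(c:1,d:1):1):1,(e:1,f:1):1,g:1);")
  abcd2 <- ape::getMRCA(phy2, c("a", "d"))
  root2 <- ape::Ntip(phy2) + 1L
  nb2 <- neighbor_branches(phy2, paste0(phy2$node.id[root2], "-",
                                        phy2$node.id[abcd2]))
  expect_equal(nrow(nb2), 3L)

  # terminal focal branch is out of scope
  expect_error(neighbor_branches(phy2, paste0(phy2$node.id[root2], "-g")),
               "terminal")
})

test_that("branch replacements respect confidence and score by BDM", {
  tr <- quartet()
  sim <- simulate_alignment(sim_config(phy = tr, L = 50L, seed = 41))
  anc <- marginal_ancestral(sim$alignment, tr, wag, g2)
  internal <- paste0(tr$node.id[5], "-", tr$node.id[6])
  br <- branch_replacements(anc, sim$alignment, tr, internal)
  expect_equal(br$R, nrow(br$sites))
  expect_equal(br$BDM, sum(br$sites$bdm))
  if (br$R > 0) {
    expect_true(all(br$sites$parent_state != br$sites$child_state))
    expect_true(all(br$sites$parent_prob > 0.5 & br$sites$child_prob > 0.5))
  }

  # hand-built case: states D (0.9) vs E (0.8) at one site, rest identical
  anc2 <- anc
  id5 <- as.character(tr$node.id[5]); id6 <- as.character(tr$node.id[6])
  anc2$map_state[id5, ] <- anc2$map_state[id6, ] <- "A"
  anc2$map_prob[id5, ] <- anc2$map_prob[id6, ] <- 0.99
  anc2$map_state[id5, 7] <- "D"; anc2$map_prob[id5, 7] <- 0.9
  anc2$map_state[id6, 7] <- "E"; anc2$map_prob[id6, 7] <- 0.8
  br2 <- branch_replacements(anc2, sim$alignment, tr, internal)
  expect_equal(br2$R, 1L)
  expect_equal(br2$BDM, 7)
  # low-confidence endpoint excludes the site regardless of states
  anc2$map_prob[id5, 7] <- 0.4
  br3 <- branch_replacements(anc2, sim$alignment, tr, internal)
  expect_equal(br3$R, 0L)
  expect_equal(br3$BDM, 0)
})

test_that("one-tail Fisher reproduces the three published control tables", {
  expect_equal(round(fisher_one_tail(c(1714, 130, 719, 79)), 2), 0.01)
  expect_equal(round(fisher_one_tail(c(719, 54, 453, 41)), 2), 0.22)
  expect_equal(round(fisher_one_tail(c(1656, 126, 1483, 112)), 2), 0.55)
})

test_that("Fisher tail agrees with enumeration for all small tables", {
  # independent oracle: direct log-binomial enumeration of the tail
  oracle <- function(a, b, c, d) {
    m <- a + c; n <- b + d; k <- a + b
    xs <- max(0, k - n):min(k, m)
    lp <- lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)
    sum(exp(lp[xs >= a]))
  }
  set.seed(2)
  worst <- 0
  for (total in c(8, 20, 40, 60)) {
    for (rep in 1:40) {
      cuts <- sort(sample(0:total, 3, replace = TRUE))
      a <- cuts[1]; b <- cuts[2] - cuts[1]; c <- cuts[3] - cuts[2]
      d <- total - cuts[3]
      if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) next
      p <- fisher_one_tail(matrix(c(a, b, c, d), 2, 2, byrow = TRUE))
      o <- oracle(a, b, c, d)
      worst <- max(worst, abs(p - o) / max(o, 1e-300))
      # and the shipped reference implementation agrees too
      ft <- fisher.test(matrix(c(a, b, c, d), 2, 2, byrow = TRUE),
                        alternative = "greater")$p.value
      expect_equal(p, ft, tolerance = 1e-9)
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("the two one-sided tails overlap by the point mass", {
  tabs <- list(c(3, 5, 7, 2), c(10, 1, 2, 9), c(4, 4, 4, 4), c(0, 6, 5, 1))
  for (x in tabs) {
    tab <- matrix(x, 2, 2, byrow = TRUE)
    p_hi <- fisher_one_tail(tab)
    p_lo <- fisher_one_tail(tab[2:1, ])        # other direction
    m <- sum(tab[, 1]); n <- sum(tab[, 2]); k <- sum(tab[1, ])
    point <- dhyper(tab[1, 1], m, n, k)
    expect_equal(p_hi + p_lo, 1 + point, tolerance = 1e-12)
  }
})

test_that("the branch contrast behaves sensibly at its boundaries", {
  # equal BDM-per-replacement with large counts: P near one half
  expect_gt(fisher_one_tail(c(1300, 100, 2600, 200)), 0.4)
  expect_lt(fisher_one_tail(c(1300, 100, 2600, 200)), 0.6)
  # doubling all cells of an enriched table never increases P
  tab <- c(200, 10, 150, 20)
  expect_lte(fisher_one_tail(2 * tab), fisher_one_tail(tab))
  expect_error(fisher_one_tail(c(-1, 2, 3, 4)), "nonnegative")
})

test_that("bdm_branch_test pools neighbors and reports evidence", {
  tr <- shifted_family_tree()
  focal <- attr(tr, "shift_branch")
  sim <- simulate_alignment(sim_config(phy = tr, L = 300L, seed = 43,
                                       shift_branch = focal, beta = 8))
  anc <- marginal_ancestral(sim$alignment, tr, wag, g2)
  res <- bdm_branch_test(anc, sim$alignment, tr, focal)
  expect_s3_class(res, "bdm_result")
  expect_equal(res$R2, sum(vapply(res$neighbor_detail, nrow, integer(1))))
  expect_equal(res$BDM2,
               sum(vapply(res$neighbor_detail, function(d) sum(d$bdm), numeric(1))))
  expect_equal(res$P,
               fisher_one_tail(c(round(res$BDM1), res$R1, round(res$BDM2), res$R2)))
  expect_true(res$P >= 0 && res$P <= 1)

  # BDM sums are invariant to a consistent column permutation
  set.seed(44)
  perm <- sample(sim$alignment$L)
  aln_p <- protein_alignment(setNames(
    apply(sim$alignment$mat[, perm, drop = FALSE], 1, paste, collapse = ""),
    sim$alignment$names))
  anc_p <- marginal_ancestral(aln_p, tr, wag, g2)
  res_p <- bdm_branch_test(anc_p, aln_p, tr, focal)
  expect_equal(res_p$BDM1, res$BDM1)
  expect_equal(res_p$R1, res$R1)
  expect_equal(res_p$P, res$P)
})

test_that("no confident replacements anywhere yields an explained NA", {
  # zero-length internal branches and identical sequences: nothing happens
  phy <- read_newick("((a:0,b:0):0,(c:0,d:0):0);")
  aln <- protein_alignment(c(a = "MKVLW", b = "MKVLW", c = "MKVLW", d = "MKVLW"))
  anc <- marginal_ancestral(aln, phy, wag, g1)
  focal <- paste0(phy$node.id[5], "-", phy$node.id[6])
  res <- suppressWarnings(bdm_branch_test(anc, aln, phy, focal))
  expect_true(is.na(res$P))
  expect_match(res$note, "undefined")
})
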