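#' Pairwise maximum-likelihood protein distances
#'
#' For each sequence pair, maximizes the two-sequence likelihood
#' `prod_sites sum_c w_c pi_a P^{(c)}(t)[a, b]` over the evolutionary
#' distance t, under the given model and rate classes. Sites where either
#' sequence has a gap or `X` are ignored (pairwise deletion). A pair with
#' no comparable sites gets `d_max` with a warning.
#'
#' @param aln A [protein_alignment()].
#' @param model A [subst_model()].
#' @param rates A [discretize_gamma()] object.
#' @param d_max Upper bound / fallback distance (substitutions per site).
#' @return A symmetric N x N distance matrix with zero diagonal.
#' @export
protein_distance <- function(aln, model, rates = discretize_gamma(1, 1L),
                             d_max = 20) {
  if (aln$N < 2L) stop("need at least 2 sequences")
  enc <- encode_alignment(aln)
  D <- matrix(0, aln$N, aln$N, dimnames = list(aln$names, aln$names))
  lpi <- log(model$pi)
  for (i in seq_len(aln$N - 1L)) {
    for (j in (i + 1L):aln$N) {
      ok <- !is.na(enc[i, ]) & !is.na(enc[j, ])
      if (!any(ok)) {
        warning("no comparable sites for pair ", aln$names[i], "/",
                aln$names[j], "; distance set to d_max")
        D[i, j] <- D[j, i] <- d_max
        next
      }
      C <- matrix(0, 20L, 20L)
      tab <- table(factor(enc[i, ok], levels = 1:20),
                   factor(enc[j, ok], levels = 1:20))
      C[] <- as.numeric(tab)
      if (sum(C * (1 - diag(20))) == 0) next  # identical -> 0
      nll <- function(t) {
        M <- 0
        for (c in seq_len(rates$k)) {
          M <- M + rates$weights[c] * transition_matrix(model, t, rates$rates[c])
        }
        -sum(C * (lpi + log(pmax(M, 1e-300))))
      }
      opt <- stats::optimize(nll, c(1e-8, d_max))
      D[i, j] <- D[j, i] <- opt$minimum
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration. A negative branch length arising at a
#' join is clamped to zero and the excess transferred to its sibling
#' branch, so the path length between the joined nodes is preserved and
#' all output branch lengths are nonnegative.
#'
#' @param D Symmetric nonnegative distance matrix (zero diagonal) with
#'   dimnames, or a `dist`.
#' @param names Taxon names (defaults to `rownames(D)`).
#' @return An unrooted `ape::phylo` with node ids assigned.
#' @export
nj_tree <- function(D, names = NULL) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix must be symmetric")
  if (is.null(names)) names <- rownames(D)
  if (is.null(names)) names <- paste0("t", seq_len(n))
  labels <- names                      # newick fragment per active cluster
  clamp_pair <- function(d, li) {
    lj <- d - li
    if (li < 0) { lj <- d; li <- 0 }
    if (lj < 0) { li <- d; lj <- 0 }
    c(li, lj)
  }
  while (n > 3L) {
    r <- rowSums(D)
    Qm <- (n - 2) * D - outer(r, r, `+`)
    diag(Qm) <- Inf
    ij <- which(Qm == min(Qm), arr.ind = TRUE)[1L, ]
    i <- min(ij); j <- max(ij)
    li <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (n - 2))
    l2 <- clamp_pair(D[i, j], li)
    newlab <- sprintf("(%s:%.10g,%s:%.10g)", labels[i], l2[1L],
                      labels[j], l2[2L])
    dnew <- 0.5 * (D[i, -c(i, j)] + D[j, -c(i, j)] - D[i, j])
    dnew[dnew < 0] <- 0
    D <- rbind(cbind(D[-c(i, j), -c(i, j), drop = FALSE], dnew),
               c(dnew, 0))
    labels <- c(labels[-c(i, j)], newlab)
    n <- n - 1L
  }
  # terminal 3-star: solve the three-point formulas
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  ls <- pmax(c(la, lb, lc), 0)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 labels[1L], ls[1L], labels[2L], ls[2L], labels[3L], ls[3L])
  read_newick(nwk)
}

#' Bootstrap support for NJ clades by alignment-column resampling
#'
#' Resamples alignment columns with replacement `B` times, rebuilds the
#' ML-distance NJ tree per replicate, and reports for each internal branch
#' of the original tree the percentage of replicate trees containing the
#' same leaf bipartition.
#'
#' @param aln,model,rates As in [protein_distance()].
#' @param B Number of bootstrap replicates (`>= 1`).
#' @param seed Integer seed; all resampling flows from it.
#' @param phy Optional tree to annotate; default is the NJ tree of the
#'   full alignment.
#' @return List with `tree` and `support`: data.frame (branch, child_id,
#'   support_pct) over internal branches.
#' @export
bootstrap_support <- function(aln, model, rates = discretize_gamma(1, 1L),
                              B = 100L, seed = 1L, phy = NULL) {
  if (B < 1L) stop("B must be >= 1")
  if (is.null(phy)) phy <- nj_tree(protein_distance(aln, model, rates))
  set.seed(seed)
  boot <- vector("list", B)
  for (b in seq_len(B)) {
    cols <- sample.int(aln$L, aln$L, replace = TRUE)
    sub <- protein_alignment(stats::setNames(
      apply(aln$mat[, cols, drop = FALSE], 1L, paste, collapse = ""),
      aln$names))
    boot[[b]] <- nj_tree(protein_distance(sub, model, rates))
  }
  counts <- ape::prop.clades(phy, boot, rooted = FALSE)
  counts[is.na(counts)] <- 0
  ntip <- ape::Ntip(phy)
  internal_nodes <- (ntip + 1L):(ntip + phy$Nnode)
  # support attaches to the edge above each internal node (skip the root)
  edge_of_node <- match(internal_nodes, phy$edge[, 2L])
  keep <- !is.na(edge_of_node)
  sup <- data.frame(
    branch = paste0(phy$node.id[phy$edge[edge_of_node[keep], 1L]], "-",
                    phy$node.id[internal_nodes[keep]]),
    child_id = phy$node.id[internal_nodes[keep]],
    support_pct = 100 * counts[keep] / B,
    stringsAsFactors = FALSE
  )
  list(tree = phy, support = sup, B = B)
}
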