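# Felsenstein pruning with per-node, per-site log scaling.
#
# Partial (conditional) likelihoods are held as 20 x L matrices per node and
# per rate category; a per-site log scaling factor accumulated along the
# traversal keeps columns in floating range regardless of sequence count, so
# reported log-likelihoods are exact up to accumulated rounding (~1e-10).

bind_alignment <- function(aln, phy) {
  if (!all(phy$tip.label %in% aln$names)) {
    stop("tree leaves not found in alignment: ",
         paste(setdiff(phy$tip.label, aln$names), collapse = ", "))
  }
  enc <- encode_alignment(aln)
  enc[phy$tip.label, , drop = FALSE]
}

# One tip's partial-likelihood matrix: indicator columns, all-ones for
# gap/'X' (missing data).
tip_partial <- function(codes, L) {
  F <- matrix(0, 20L, L)
  obs <- which(!is.na(codes))
  F[cbind(codes[obs], obs)] <- 1
  if (length(obs) < L) F[, setdiff(seq_len(L), obs)] <- 1
  F
}

# Rescale columns of a partial matrix; returns the matrix and per-site log
# scaling increments.
rescale_cols <- function(F) {
  s <- F[cbind(max.col(t(F), ties.method = "first"), seq_len(ncol(F)))]
  s[s <= 0] <- 1
  list(F = F / rep(s, each = nrow(F)), logs = log(s))
}

# Full downward (tips -> root) pruning pass.
# Returns per-category partials and scalers for every node, the transition
# matrices per edge x category, per-category per-site log-likelihoods, the
# mixed per-site log-likelihood, and the total lnL.
pruning_pass <- function(enc, phy, model, rates, keep_partials = TRUE) {
  ntip <- nrow(enc); L <- ncol(enc); k <- rates$k
  po <- ape::reorder.phylo(phy, "postorder")
  nnode <- ntip + phy$Nnode
  P <- vector("list", nrow(po$edge))          # [[edge]][[cat]]
  Fs <- vector("list", nnode)                 # [[node]][[cat]] 20 x L
  logs <- vector("list", nnode)               # [[node]][[cat]] length L
  for (tip in seq_len(ntip)) {
    Ftip <- tip_partial(enc[tip, ], L)
    Fs[[tip]] <- rep(list(Ftip), k)
    logs[[tip]] <- rep(list(numeric(L)), k)
  }
  parents <- unique(po$edge[, 1L])
  kids <- split(seq_len(nrow(po$edge)), po$edge[, 1L])
  for (u in parents) {
    Fu <- vector("list", k); lu <- vector("list", k)
    for (c in seq_len(k)) {
      acc <- NULL; lacc <- numeric(L)
      for (e in kids[[as.character(u)]]) {
        v <- po$edge[e, 2L]
        if (is.null(P[[e]])) P[[e]] <- vector("list", k)
        Pe <- transition_matrix(model, po$edge.length[e], rates$rates[c])
        P[[e]][[c]] <- Pe
        contrib <- Pe %*% Fs[[v]][[c]]
        acc <- if (is.null(acc)) contrib else acc * contrib
        lacc <- lacc + logs[[v]][[c]]
      }
      sc <- rescale_cols(acc)
      Fu[[c]] <- sc$F
      lu[[c]] <- lacc + sc$logs
    }
    Fs[[u]] <- Fu; logs[[u]] <- lu
  }
  root <- ntip + 1L
  cat_ll <- matrix(0, k, L)
  for (c in seq_len(k)) {
    cat_ll[c, ] <- log(colSums(model$pi * Fs[[root]][[c]])) + logs[[root]][[c]]
  }
  m <- apply(cat_ll, 2L, max)
  site_ll <- m + log(colSums(rates$weights * exp(cat_ll - rep(m, each = k))))
  list(edge_tree = po, P = P, F = if (keep_partials) Fs else NULL,
       logs = if (keep_partials) logs else NULL,
       cat_ll = cat_ll, site_ll = site_ll, lnL = sum(site_ll), root = root)
}

#' Per-site log-likelihoods of an alignment on a tree
#'
#' Computes the discrete-Gamma mixture likelihood
#' `L(site) = sum_c (1/k) sum_s pi_s F_s^{(c)}` by the pruning algorithm
#' with per-site scaling (no underflow for any sequence count).
#'
#' @param aln A [protein_alignment()].
#' @param phy Tree whose tip labels all occur in `aln`.
#' @param model A [subst_model()].
#' @param rates A [discretize_gamma()] object.
#' @return List with `site_lnL` (length-L vector) and total `lnL`.
#' @export
site_log_likelihood <- function(aln, phy, model, rates = discretize_gamma(1, 1L)) {
  enc <- bind_alignment(aln, phy)
  if (ape::Ntip(phy) == 1L || is.null(phy$edge) || nrow(phy$edge) == 0L) {
    stop("tree must have at least 2 tips joined by branches")
  }
  pp <- pruning_pass(enc, phy, model, rates, keep_partials = FALSE)
  list(site_lnL = pp$site_ll, lnL = pp$lnL)
}

# Upward ("above") partials A for every node, per category, from a completed
# pruning pass. A[root] = pi; for child v of u with edge matrix P_e and
# siblings w: A_v = t(P_e) %*% (A_u * prod_w (P_w F_w)). Scaled like F.
upward_pass <- function(pp, model, rates) {
  po <- pp$edge_tree
  ntip <- length(po$tip.label); L <- length(pp$site_ll); k <- rates$k
  nnode <- ntip + po$Nnode
  A <- vector("list", nnode); logsA <- vector("list", nnode)
  root <- pp$root
  A[[root]] <- rep(list(matrix(model$pi, 20L, L)), k)
  logsA[[root]] <- rep(list(numeric(L)), k)
  kids <- split(seq_len(nrow(po$edge)), po$edge[, 1L])
  # preorder: reverse of postorder edge order visits parents before children
  for (e in rev(seq_len(nrow(po$edge)))) {
    u <- po$edge[e, 1L]; v <- po$edge[e, 2L]
    Av <- vector("list", k); lv <- vector("list", k)
    for (c in seq_len(k)) {
      S <- A[[u]][[c]]
      lacc <- logsA[[u]][[c]]
      for (e2 in kids[[as.character(u)]]) {
        if (e2 == e) next
        w <- po$edge[e2, 2L]
        S <- S * (pp$P[[e2]][[c]] %*% pp$F[[w]][[c]])
        lacc <- lacc + pp$logs[[w]][[c]]
      }
      sc <- rescale_cols(crossprod(pp$P[[e]][[c]], S))
      Av[[c]] <- sc$F
      lv[[c]] <- lacc + sc$logs
    }
    A[[v]] <- Av; logsA[[v]] <- lv
  }
  list(A = A, logsA = logsA)
}

#' Optimize branch lengths on a fixed topology
#'
#' Coordinate-wise bounded 1-D optimization (Brent) of each branch length
#' in post-order sweeps, each sweep refreshing the surrounding conditional
#' likelihoods so every accepted update increases the likelihood; cycles
#' stop when the total log-likelihood improves by less than `tol`.
#'
#' @param aln,phy,model,rates As in [site_log_likelihood()].
#' @param tol Convergence tolerance on lnL (default 1e-6).
#' @param max_cycles Maximum sweeps; non-convergence sets a warning flag on
#'   the result rather than failing.
#' @param upper Upper bound on a branch length (substitutions/site).
#' @return List with `tree` (optimized lengths), `lnL`, `converged`,
#'   `cycles`.
#' @export
optimize_branch_lengths <- function(aln, phy, model, rates = discretize_gamma(1, 1L),
                                    tol = 1e-6, max_cycles = 25L, upper = 20) {
  enc <- bind_alignment(aln, phy)
  k <- rates$k
  lw <- log(rates$weights)
  lnL_prev <- -Inf
  converged <- FALSE
  cycles <- 0L
  for (cycle in seq_len(max_cycles)) {
    cycles <- cycle
    for (e in seq_len(nrow(phy$edge))) {
      # refresh all conditionals so this edge's 1-D profile is exact:
      # every accepted update then increases the true likelihood
      pp <- pruning_pass(enc, phy, model, rates)
      up <- upward_pass(pp, model, rates)
      po <- pp$edge_tree
      kids <- split(seq_len(nrow(po$edge)), po$edge[, 1L])
      u <- po$edge[e, 1L]; v <- po$edge[e, 2L]
      # parent-side context B and child-side F for this edge, per category
      B <- vector("list", k); lB <- vector("list", k)
      for (c in seq_len(k)) {
        S <- up$A[[u]][[c]]; lacc <- up$logsA[[u]][[c]]
        for (e2 in kids[[as.character(u)]]) {
          if (e2 == e) next
          w <- po$edge[e2, 2L]
          S <- S * (pp$P[[e2]][[c]] %*% pp$F[[w]][[c]])
          lacc <- lacc + pp$logs[[w]][[c]]
        }
        B[[c]] <- S; lB[[c]] <- lacc + pp$logs[[v]][[c]]
      }
      Fv <- lapply(seq_len(k), function(c) pp$F[[v]][[c]])
      edge_lnL <- function(t) {
        cl <- vapply(seq_len(k), function(c) {
          Pe <- transition_matrix(model, t, rates$rates[c])
          lik <- colSums(B[[c]] * (Pe %*% Fv[[c]]))
          log(pmax(lik, 1e-300)) + lB[[c]] + lw[c]
        }, numeric(length(pp$site_ll)))
        if (k == 1L) sum(cl) else {
          m <- apply(cl, 1L, max)
          sum(m + log(rowSums(exp(cl - m))))
        }
      }
      opt <- stats::optimize(edge_lnL, c(0, upper), maximum = TRUE, tol = 1e-8)
      cur <- edge_lnL(po$edge.length[e])
      # also probe 0 exactly: Brent can miss a boundary optimum
      at0 <- edge_lnL(0)
      best_t <- if (at0 >= opt$objective) 0 else opt$maximum
      best <- max(at0, opt$objective)
      if (best > cur) {
        po$edge.length[e] <- best_t
        phy <- copy_edge_lengths(phy, po)
      }
    }
    lnL <- pruning_pass(enc, phy, model, rates, keep_partials = FALSE)$lnL
    if (abs(lnL - lnL_prev) < tol) { converged <- TRUE; lnL_prev <- lnL; break }
    lnL_prev <- lnL
  }
  list(tree = phy, lnL = lnL_prev, converged = converged, cycles = cycles)
}

# Copy edge lengths from a reordered copy back onto the original ordering.
copy_edge_lengths <- function(phy, po) {
  key_po <- paste(po$edge[, 1L], po$edge[, 2L])
  key <- paste(phy$edge[, 1L], phy$edge[, 2L])
  phy$edge.length <- po$edge.length[match(key, key_po)]
  phy
}
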