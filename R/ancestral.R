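#' Marginal maximum-likelihood ancestral state reconstruction
#'
#' For every internal node and alignment column, computes the posterior
#' distribution over the 20 amino acids given all tip data, the tree, the
#' substitution model and the discrete-Gamma rates: the standard up-down
#' (inside-outside) algorithm, run per rate category and mixed across
#' categories by each site's posterior category weights
#' `w_c L_c(site) / sum_c' w_c' L_c'(site)` (empirical-Bayes treatment).
#'
#' Posteriors are invariant to root placement under these reversible
#' models. Tips are observed, not reconstructed.
#'
#' @param aln A [protein_alignment()].
#' @param phy Tree with branch lengths (typically from
#'   [optimize_branch_lengths()]) and node ids.
#' @param model A [subst_model()].
#' @param rates A [discretize_gamma()] object.
#' @return An `ancestral_states` object: list with
#'   \describe{
#'     \item{node_ids}{stable ids of the internal nodes, post-order;}
#'     \item{posterior}{named list of 20 x L posterior matrices per node;}
#'     \item{map_state}{matrix (nodes x L) of argmax residues;}
#'     \item{map_prob}{matrix (nodes x L) of their posterior probabilities;}
#'     \item{lnL}{total log-likelihood of the data.}
#'   }
#' @export
marginal_ancestral <- function(aln, phy, model, rates = discretize_gamma(1, 1L)) {
  enc <- bind_alignment(aln, phy)
  pp <- pruning_pass(enc, phy, model, rates)
  up <- upward_pass(pp, model, rates)
  po <- pp$edge_tree
  ntip <- ape::Ntip(phy); L <- aln$L; k <- rates$k
  internal <- (ntip + 1L):(ntip + phy$Nnode)
  # per-site posterior weight of each category
  wpost <- exp(pp$cat_ll + log(rates$weights) -
                 rep(pp$site_ll, each = k))  # k x L
  ids <- phy$node.id[internal]
  posterior <- vector("list", length(internal))
  names(posterior) <- as.character(ids)
  map_state <- matrix(NA_character_, length(internal), L,
                      dimnames = list(as.character(ids), NULL))
  map_prob <- matrix(NA_real_, length(internal), L,
                     dimnames = list(as.character(ids), NULL))
  for (i in seq_along(internal)) {
    v <- internal[i]
    post <- matrix(0, 20L, L)
    for (c in seq_len(k)) {
      raw <- pp$F[[v]][[c]] * up$A[[v]][[c]]
      cs <- colSums(raw)
      cs[cs <= 0] <- 1
      post <- post + rep(wpost[c, ], each = 20L) * (raw / rep(cs, each = 20L))
    }
    rownames(post) <- AA20
    posterior[[i]] <- post
    amax <- max.col(t(post), ties.method = "first")
    map_state[i, ] <- AA20[amax]
    map_prob[i, ] <- post[cbind(amax, seq_len(L))]
  }
  structure(list(node_ids = ids, posterior = posterior,
                 map_state = map_state, map_prob = map_prob,
                 lnL = pp$lnL, L = L),
            class = "ancestral_states")
}

#' High-confidence ancestral sequences with low-confidence sites masked
#'
#' A site in an ancestral sequence is reported only when its maximum
#' posterior probability exceeds `threshold` (strictly, by default:
#' `prob > 0.5` keeps a site, `prob == 0.5` masks it); masked sites are
#' shown as `'x'`.
#'
#' @param anc An [marginal_ancestral()] result.
#' @param threshold Probability cutoff in `[0, 1)`; default 0.5.
#' @param inclusive If `TRUE`, keep sites with `prob >= threshold` instead
#'   of the default strict `>`.
#' @return List with `sequences` (named character vector, one per internal
#'   node) and `table` (data.frame: node, site, map_state, map_prob,
#'   masked).
#' @export
ancestral_sequence_report <- function(anc, threshold = 0.5, inclusive = FALSE) {
  if (threshold < 0 || threshold >= 1) stop("threshold must be in [0, 1)")
  keep <- if (inclusive) anc$map_prob >= threshold else anc$map_prob > threshold
  chars <- anc$map_state
  chars[!keep] <- "x"
  seqs <- apply(chars, 1L, paste, collapse = "")
  tab <- data.frame(
    node = rep(rownames(anc$map_state), anc$L),
    site = rep(seq_len(anc$L), each = nrow(anc$map_state)),
    map_state = as.vector(anc$map_state),
    map_prob = as.vector(anc$map_prob),
    masked = as.vector(!keep),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$node, tab$site), ]
  rownames(tab) <- NULL
  list(sequences = seqs, table = tab, threshold = threshold,
       inclusive = inclusive)
}
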