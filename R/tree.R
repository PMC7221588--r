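#' Read a Newick tree and assign stable node identifiers
#'
#' Trees are stored as `ape::phylo` objects augmented with a `node.id`
#' component: every node (tip or internal) carries a stable integer
#' identifier echoed in all reports, so branches can be referenced as
#' `"374-375"` strings. Tips are numbered 1..N in the order they appear in
#' the file; internal nodes are numbered in post-order starting at `offset`
#' (default N+1). Internal labels already present in the file (e.g.
#' bootstrap supports) are preserved in `node.label`.
#'
#' Missing branch lengths are set to 0. Negative branch lengths are
#' rejected.
#'
#' @param path Path to a Newick file (or a literal Newick string containing
#'   a semicolon).
#' @param offset First integer id for internal nodes; default `Ntip + 1`.
#' @return An `ape::phylo` with a `node.id` integer vector indexed by ape
#'   node number.
#' @export
read_newick <- function(path, offset = NULL) {
  phy <- if (grepl(";", path, fixed = TRUE)) {
    ape::read.tree(text = path)
  } else {
    if (!file.exists(path)) stop("file not found: ", path)
    ape::read.tree(path)
  }
  if (is.null(phy)) stop("could not parse Newick input")
  if (is.null(phy$edge.length)) phy$edge.length <- rep(0, nrow(phy$edge))
  phy$edge.length[is.na(phy$edge.length)] <- 0
  if (any(phy$edge.length < 0)) {
    stop("negative branch length in tree (lengths must be >= 0)")
  }
  assign_node_ids(phy, offset = offset)
}

#' Assign deterministic integer node ids to a tree
#'
#' @param phy An `ape::phylo`.
#' @param offset First id for internal nodes (default `Ntip + 1`).
#' @return `phy` with a `node.id` component.
#' @export
assign_node_ids <- function(phy, offset = NULL) {
  ntip <- ape::Ntip(phy)
  if (is.null(offset)) offset <- ntip + 1L
  ids <- integer(ntip + phy$Nnode)
  ids[seq_len(ntip)] <- seq_len(ntip)
  po <- ape::reorder.phylo(phy, "postorder")
  internal_order <- unique(po$edge[, 1L])  # parents in post-order visit order
  # the root appears last in post-order edge parents; include any isolated root
  internal_order <- c(internal_order,
                      setdiff((ntip + 1L):(ntip + phy$Nnode), internal_order))
  ids[internal_order] <- seq.int(offset, length.out = phy$Nnode)
  phy$node.id <- ids
  phy
}

# ape node number -> stable id, and the inverse lookup
node_id_of <- function(phy, node) phy$node.id[node]

node_of_id <- function(phy, id) {
  hit <- which(phy$node.id == id)
  if (length(hit) != 1L) stop("unknown node id: ", id)
  hit
}

#' Resolve a branch reference to an edge of the tree
#'
#' Accepts a `"parentId-childId"` string (ids as printed by
#' [tree_branch_table()]), a leaf name in place of an id, or a length-2
#' vector of ids. The pair may be given in either order.
#'
#' @param phy Tree with node ids.
#' @param branch Branch reference.
#' @return List with ape node numbers `parent`, `child`, edge row `edge`,
#'   and the id string `label`.
#' @export
resolve_branch <- function(phy, branch) {
  if (is.character(branch) && length(branch) == 1L && grepl("-", branch)) {
    branch <- strsplit(branch, "-", fixed = TRUE)[[1L]]
  }
  if (length(branch) != 2L) stop("branch must be a 'parentId-childId' pair")
  to_node <- function(tok) {
    tok <- trimws(tok)
    if (tok %in% phy$tip.label) return(match(tok, phy$tip.label))
    node_of_id(phy, as.integer(tok))
  }
  a <- to_node(branch[[1L]]); b <- to_node(branch[[2L]])
  e <- which((phy$edge[, 1L] == a & phy$edge[, 2L] == b) |
             (phy$edge[, 1L] == b & phy$edge[, 2L] == a))
  if (length(e) != 1L) {
    stop("no branch joins nodes ", branch[[1L]], " and ", branch[[2L]])
  }
  list(parent = phy$edge[e, 1L], child = phy$edge[e, 2L], edge = e,
       label = paste0(phy$node.id[phy$edge[e, 1L]], "-",
                      phy$node.id[phy$edge[e, 2L]]))
}

#' Tabulate the branches of a tree with their stable ids
#'
#' @param phy Tree with node ids.
#' @return data.frame with parent/child ids, labels, branch lengths, and a
#'   flag for terminal (leaf-incident) branches.
#' @export
tree_branch_table <- function(phy) {
  ntip <- ape::Ntip(phy)
  data.frame(
    branch = paste0(phy$node.id[phy$edge[, 1L]], "-",
                    phy$node.id[phy$edge[, 2L]]),
    parent_id = phy$node.id[phy$edge[, 1L]],
    child_id = phy$node.id[phy$edge[, 2L]],
    child_name = ifelse(phy$edge[, 2L] <= ntip,
                        phy$tip.label[pmin(phy$edge[, 2L], ntip)], NA),
    length = phy$edge.length,
    terminal = phy$edge[, 2L] <= ntip,
    stringsAsFactors = FALSE
  )
}

#' Write a Newick string with per-node annotations as comments
#'
#' Annotations are emitted as `[...]` comments after the node they refer
#' to; the result round-trips through [read_newick()] (which, like ape,
#' discards comments), preserving topology, leaf names and branch lengths.
#'
#' @param phy Tree with node ids.
#' @param annotations Named character vector or list: names are node ids
#'   (or tip labels), values the annotation text.
#' @param path Output file; if `NULL` the Newick string is returned.
#' @return The Newick string, invisibly if written to file.
#' @export
write_annotated_newick <- function(phy, annotations = NULL, path = NULL) {
  ann <- character(ape::Ntip(phy) + phy$Nnode)
  if (length(annotations)) {
    keys <- names(annotations)
    if (is.null(keys)) stop("annotations must be named by node id")
    for (i in seq_along(annotations)) {
      node <- if (keys[i] %in% phy$tip.label) {
        match(keys[i], phy$tip.label)
      } else {
        node_of_id(phy, as.integer(keys[i]))
      }
      ann[node] <- paste0("[", annotations[[i]], "]")
    }
  }
  ntip <- ape::Ntip(phy)
  kids <- split(seq_len(nrow(phy$edge)), phy$edge[, 1L])
  fmt_bl <- function(e) {
    if (is.null(phy$edge.length)) "" else
      paste0(":", format(phy$edge.length[e], digits = 10, trim = TRUE,
                         scientific = FALSE))
  }
  rec <- function(node, edge_in) {
    body <- if (node <= ntip) {
      phy$tip.label[node]
    } else {
      sub <- vapply(kids[[as.character(node)]],
                    function(e) rec(phy$edge[e, 2L], e), character(1))
      paste0("(", paste(sub, collapse = ","), ")")
    }
    paste0(body, ann[node], if (is.na(edge_in)) "" else fmt_bl(edge_in))
  }
  s <- paste0(rec(ntip + 1L, NA), ";")
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Generate a balanced (fully bifurcating) tree for simulations
#'
#' @param n_taxa Number of tips (rounded up to a power of two shape by
#'   repeated splitting; exact tip count is honored).
#' @param depth Total root-to-tip path length, split evenly across levels.
#' @return An `ape::phylo` with node ids assigned.
#' @export
balanced_tree <- function(n_taxa, depth = 1) {
  if (n_taxa < 2) stop("need at least 2 taxa")
  levels <- ceiling(log2(n_taxa))
  bl <- format(depth / max(levels, 1), digits = 10, scientific = FALSE)
  counter <- 0L
  rec <- function(n) {
    if (n == 1L) {
      counter <<- counter + 1L
      return(sprintf("t%02d:%s", counter, bl))
    }
    a <- ceiling(n / 2); b <- n - a
    paste0("(", rec(a), ",", rec(b), "):", bl)
  }
  core <- if (n_taxa == 2L) {
    paste0("(", rec(1L), ",", rec(1L), ")")
  } else {
    a <- ceiling(n_taxa / 2); b <- n_taxa - a
    paste0("(", rec(a), ",", rec(b), ")")
  }
  read_newick(paste0(core, ";"))
}
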