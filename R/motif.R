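# PROSITE-style motif expression -> regular expression over amino acids.
# Supported syntax: fixed letters, x wildcards, x(n) repeats, [ABC]
# alternatives, {ABC} exclusions, '-' element separators.
motif_to_regex <- function(pattern) {
  p <- gsub("-", "", toupper(pattern))
  p <- gsub("X\\((\\d+)\\)", ".{\\1}", p)
  p <- gsub("X", ".", p)
  p <- gsub("\\{([A-Z]+)\\}", "[^\\1]", p)
  if (!grepl("^([A-Z.]|\\[[\\^A-Z]+\\]|\\.\\{\\d+\\})+$", p)) {
    stop("malformed motif pattern: ", pattern)
  }
  p
}

#' Scan aligned sequences for a short conserved motif
#'
#' Scans each sequence with gaps removed, reporting all non-overlapping
#' (leftmost-wins) matches of a PROSITE-style pattern — e.g. `"PDPCK"`,
#' the conserved animal carotenoid-oxygenase palmitoylation motif, or
#' `"[PS]DPCK"` to also catch the serine variant. Positions are reported
#' both as 1-based ungapped sequence positions and as alignment columns.
#'
#' @param aln A [protein_alignment()].
#' @param pattern Motif expression (fixed letters, `[..]` alternatives,
#'   `x` wildcards).
#' @return data.frame of hits: seq_id, pattern, start, end (ungapped),
#'   aln_start, aln_end (columns), match, exact (FALSE when the pattern
#'   has wildcards/alternatives).
#' @export
scan_motif <- function(aln, pattern) {
  rx <- motif_to_regex(pattern)
  exact <- !grepl("[", rx, fixed = TRUE) && !grepl(".", rx, fixed = TRUE)
  out <- list()
  for (i in seq_len(aln$N)) {
    ug <- ungap(aln$seqs[i])
    if (!nzchar(ug$seq)) next
    m <- gregexpr(rx, ug$seq, perl = TRUE)[[1L]]
    if (m[1L] == -1L) next
    len <- attr(m, "match.length")
    out[[length(out) + 1L]] <- data.frame(
      seq_id = aln$names[i], pattern = pattern,
      start = as.integer(m), end = as.integer(m) + len - 1L,
      aln_start = ug$cols[as.integer(m)],
      aln_end = ug$cols[as.integer(m) + len - 1L],
      match = substring(ug$seq, m, m + len - 1L),
      exact = exact, stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    return(data.frame(seq_id = character(0), pattern = character(0),
                      start = integer(0), end = integer(0),
                      aln_start = integer(0), aln_end = integer(0),
                      match = character(0), exact = logical(0)))
  }
  do.call(rbind, out)
}

#' Residues of every sequence at reference-anchored columns
#'
#' Maps 1-based ungapped positions of a reference sequence (e.g. the four
#' canonical iron-coordinating histidines, or the PDPCK cysteine C111 of
#' mouse BCO2) to alignment columns and reports each sequence's residue
#' there, with conservation counts relative to the reference residue.
#'
#' @param aln A [protein_alignment()].
#' @param reference Reference sequence id.
#' @param positions Integer vector of 1-based ungapped reference positions.
#' @return List with `residues` (data.frame: position, column, ref_residue,
#'   then one column per sequence) and `conservation` (data.frame:
#'   position, column, ref_residue, n_conserved, n_gap, n_total).
#' @export
conserved_column_report <- function(aln, reference, positions) {
  ri <- match(reference, aln$names)
  if (is.na(ri)) stop("reference id not in alignment: ", reference)
  ug <- ungap(aln$seqs[ri])
  if (any(positions < 1L | positions > nchar(ug$seq))) {
    stop("position beyond ungapped reference length (", nchar(ug$seq), ")")
  }
  cols <- ug$cols[positions]
  refres <- substring(ug$seq, positions, positions)
  resmat <- aln$mat[, cols, drop = FALSE]
  residues <- data.frame(position = positions, column = cols,
                         ref_residue = refres, stringsAsFactors = FALSE)
  for (i in seq_len(aln$N)) residues[[aln$names[i]]] <- resmat[i, ]
  conservation <- data.frame(
    position = positions, column = cols, ref_residue = refres,
    n_conserved = vapply(seq_along(cols), function(j) {
      sum(resmat[, j] == refres[j])
    }, integer(1)),
    n_gap = vapply(seq_along(cols), function(j) sum(resmat[, j] == "-"),
                   integer(1)),
    n_total = aln$N, stringsAsFactors = FALSE
  )
  list(residues = residues, conservation = conservation)
}

#' Motif presence/absence summarized per named clade
#'
#' @param phy Tree whose tips cover the clade members.
#' @param hits A [scan_motif()] result.
#' @param clades Named list of character vectors of tip labels.
#' @return data.frame: clade, n, n_with_motif, fraction, monophyletic.
#' @export
clade_motif_table <- function(phy, hits, clades) {
  if (!length(clades)) {
    return(data.frame(clade = character(0), n = integer(0),
                      n_with_motif = integer(0), fraction = numeric(0),
                      monophyletic = logical(0)))
  }
  if (is.null(names(clades))) stop("clades must be a named list")
  carriers <- unique(hits$seq_id)
  rows <- lapply(names(clades), function(cl) {
    tips <- clades[[cl]]
    missing <- setdiff(tips, phy$tip.label)
    if (length(missing)) {
      stop("clade '", cl, "' contains unknown leaves: ",
           paste(missing, collapse = ", "))
    }
    data.frame(
      clade = cl, n = length(tips),
      n_with_motif = sum(tips %in% carriers),
      fraction = mean(tips %in% carriers),
      monophyletic = length(tips) == 1L ||
        ape::is.monophyletic(phy, tips, reroot = TRUE),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
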