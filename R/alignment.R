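# 20 standard amino acids, PAML/dat ordering. All model matrices, score
# matrices and partial-likelihood vectors index residues in this order.
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

ALN_ALPHABET <- c(AA20, "-", "X")

#' Construct a validated protein alignment
#'
#' A `protein_alignment` holds N aligned amino-acid sequences of equal length
#' L over the 20-letter alphabet plus gap (`-`) and unknown (`X`). Input is
#' case-normalized to upper case; `.` and `*` gap variants are normalized to
#' `-`.
#'
#' @param seqs Named character vector of aligned sequences (names are
#'   sequence identifiers).
#' @return An object of class `protein_alignment` with elements `names`,
#'   `seqs` (character vector), `mat` (N x L character matrix), `N`, `L`.
#' @export
protein_alignment <- function(seqs) {
  if (length(seqs) < 1L) stop("alignment must contain at least one sequence")
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("every sequence must carry a nonempty identifier")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(seqs)
  seqs <- gsub("[.*]", "-", seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    bad <- ids[lens != lens[1L]][1L]
    stop("ragged alignment: record '", bad, "' has length ",
         lens[ids == bad][1L], ", expected ", lens[1L])
  }
  L <- unname(lens[1L])
  if (L < 1L) stop("alignment length must be >= 1")
  mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                nrow = length(seqs), ncol = L, byrow = TRUE)
  bad <- matrix(!(mat %in% ALN_ALPHABET), nrow = nrow(mat))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop("illegal character '", mat[idx[1L], idx[2L]], "' in record '",
         ids[idx[1L]], "' at column ", idx[2L])
  }
  structure(
    list(names = unname(ids), seqs = unname(seqs), mat = mat,
         N = length(seqs), L = L),
    class = "protein_alignment"
  )
}

#' Read an aligned protein FASTA file
#'
#' @param path Path to a FASTA file of aligned amino-acid sequences.
#' @return A [protein_alignment()].
#' @export
read_fasta_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- ape::read.FASTA(path, type = "AA")
  if (length(recs) == 0L) stop("no FASTA records in ", path)
  chars <- as.character(recs)  # list of per-record character vectors
  seqs <- vapply(chars, function(x) paste(toupper(x), collapse = ""),
                 character(1))
  names(seqs) <- names(recs)
  protein_alignment(seqs)
}

#' Write a protein alignment (or named sequences) to FASTA
#'
#' @param x A `protein_alignment` or named character vector of sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "protein_alignment")) {
    ids <- x$names; seqs <- x$seqs
  } else {
    ids <- names(x); seqs <- as.character(x)
  }
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  invisible(path)
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat("protein_alignment:", x$N, "sequences x", x$L, "columns\n")
  show <- utils::head(x$names, 6L)
  for (id in show) {
    s <- x$seqs[match(id, x$names)]
    cat(sprintf("  %-20s %s%s\n", id, substr(s, 1L, 50L),
                if (x$L > 50L) "..." else ""))
  }
  if (x$N > 6L) cat("  ...", x$N - 6L, "more\n")
  invisible(x)
}

# Integer-encode an alignment: 1..20 for residues (AA20 order), NA for gap/X.
encode_alignment <- function(aln) {
  m <- matrix(match(aln$mat, AA20), nrow = aln$N)
  rownames(m) <- aln$names
  m
}

# Drop gap columns from one sequence string, returning the ungapped string
# and the mapping ungapped position -> alignment column.
ungap <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  keep <- chars != "-"
  list(seq = paste(chars[keep], collapse = ""), cols = which(keep))
}
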