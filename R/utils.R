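## CIGAR and small-sequence helpers shared by all modules.
## All coordinates are 0-based half-open internally; 1-based conversion
## happens only at the SAM/VCF boundaries.

QUERY_OPS <- c("M", "=", "X", "I", "S")
REF_OPS   <- c("M", "=", "X", "D")

#' Parse a CIGAR string into op/length vectors
#'
#' @param cigar CIGAR string, e.g. "100M2I50M".
#' @return list with character vector `op` and integer vector `len`.
#' @keywords internal
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*" || !nzchar(cigar)) {
    return(list(op = character(0), len = integer(0)))
  }
  len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  op <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  stopifnot(length(op) == length(len))
  list(op = op, len = len)
}

cigar_string <- function(cig) {
  if (length(cig$op) == 0L) return("*")
  paste0(cig$len, cig$op, collapse = "")
}

cigar_ref_len <- function(cig) sum(cig$len[cig$op %in% REF_OPS])
cigar_query_len <- function(cig) sum(cig$len[cig$op %in% QUERY_OPS])

## Collapse adjacent ops of the same type; drop zero-length ops.
cigar_canonical <- function(cig) {
  keep <- cig$len > 0L
  op <- cig$op[keep]; len <- cig$len[keep]
  if (length(op) == 0L) return(list(op = op, len = len))
  grp <- cumsum(c(TRUE, op[-1L] != op[-length(op)]))
  list(op = op[!duplicated(grp)],
       len = as.integer(tapply(len, grp, sum)))
}

#' Query offset aligned at a reference position
#'
#' Walks the CIGAR to find the 0-based query offset of the base aligned at
#' reference position `ref_pos` (alignment starting at `aln_start`). If
#' `ref_pos` falls inside a deletion the offset of the next aligned query
#' base is returned. NA when `ref_pos` lies outside the aligned span.
#' @keywords internal
query_pos_at_ref <- function(cig, aln_start, ref_pos) {
  q <- 0L; r <- aln_start
  for (i in seq_along(cig$op)) {
    op <- cig$op[i]; l <- cig$len[i]
    if (op %in% c("M", "=", "X")) {
      if (ref_pos < r + l) {
        if (ref_pos < r) return(NA_integer_)
        return(q + (ref_pos - r))
      }
      q <- q + l; r <- r + l
    } else if (op == "D" || op == "N") {
      if (ref_pos < r + l) return(q)  # inside deletion: next aligned base
      r <- r + l
    } else if (op %in% c("I", "S")) {
      q <- q + l
    }
  }
  NA_integer_
}

aln_ref_end <- function(aln) aln$start + cigar_ref_len(aln$cigar)

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(s) {
  if (!nzchar(s)) return(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

## Edit distance between two strings (plain Levenshtein).
edit_dist <- function(a, b) {
  as.integer(utils::adist(a, b))
}

phred_floor <- function(posterior, cap = 999L) {
  err <- 1 - posterior
  if (err <= 0) return(cap)
  min(cap, max(0L, as.integer(floor(-10 * log10(err)))))
}

## Simple union-find used by the clustering and merging steps.
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i); rj <- uf_find(parent, j)
  if (ri != rj) parent[ri] <- rj
  parent
}
uf_components <- function(parent) {
  roots <- vapply(seq_along(parent), function(i) uf_find(parent, i), integer(1))
  match(roots, unique(roots))
}
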