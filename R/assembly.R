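## Local consensus assembly: supporting-read segments of a cluster are
## partitioned into allele groups and each group is collapsed to a single
## polished sequence by star alignment against a backbone segment with
## per-column majority voting (including insertion slots). This meets the
## consensus-engine contract: identical inputs reproduce themselves,
## singleton errors are voted out, and at most `max_haplotypes` sequences
## are returned per cluster.

.subst_mat <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -4, baseOnly = TRUE)
    m
  }
})

align_global <- function(pattern, subject) {
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(pattern), Biostrings::DNAString(subject),
    type = "global", substitutionMatrix = .subst_mat(),
    gapOpening = 6, gapExtension = 1)
}

#' Extract orientation-normalized read segments over a cluster window
#'
#' For each supporting read of the cluster, returns the query subsequence
#' whose alignment projects onto the cluster span padded by `flank` on each
#' side (clipped at contig ends). Sequences are returned on the reference
#' strand (the orientation stored in BAM). Reads that do not fully span the
#' window are excluded.
#'
#' @param cluster a `SignatureCluster`.
#' @param alns list of `ReadAlignment` overlapping the cluster (primary
#'   records are used for sequence extraction).
#' @param flank padding in bp (default 500).
#' @param contig_len contig length used to clip the window.
#' @return list(window = c(start, end), segments = named character vector
#'   keyed by read_id).
#' @export
extract_read_segments <- function(cluster, alns, flank = 500L,
                                  contig_len = NULL) {
  ws <- max(0L, cluster$span[["start"]] - as.integer(flank))
  we <- cluster$span[["end"]] + as.integer(flank)
  if (!is.null(contig_len)) we <- min(we, as.integer(contig_len))
  support <- unique(cluster$members$read_id[cluster$members$kind != "SOFTCLIP"])
  segs <- character(0)
  for (rid in support) {
    prim <- NULL
    for (a in alns) {
      if (a$read_id == rid && is.na(a$supplementary_of) &&
          a$contig == cluster$contig && nzchar(a$seq)) { prim <- a; break }
    }
    if (is.null(prim)) next
    if (prim$start > ws || aln_ref_end(prim) < we) next  # must span window
    qs <- query_pos_at_ref(prim$cigar, prim$start, ws)
    qe <- if (aln_ref_end(prim) == we) {
      cigar_query_len(prim$cigar) -
        (if (prim$cigar$op[length(prim$cigar$op)] == "S")
          prim$cigar$len[length(prim$cigar$op)] else 0L)
    } else {
      query_pos_at_ref(prim$cigar, prim$start, we)
    }
    if (is.na(qs) || is.na(qe) || qe <= qs) next
    segs[rid] <- substr(prim$seq, qs + 1L, qe)
  }
  list(window = c(start = ws, end = we), segments = segs)
}

## Pairwise dissimilarity (edit distance / mean length) with a cheap length
## gate; long near-equal pairs are approximated on head+tail chunks.
segment_dist <- function(a, b, split_threshold) {
  la <- nchar(a); lb <- nchar(b); ml <- (la + lb) / 2
  len_ratio <- abs(la - lb) / ml
  if (len_ratio > split_threshold) return(len_ratio)
  if (ml <= 4000) return(edit_dist(a, b) / ml)
  k <- 2000L
  d <- edit_dist(substr(a, 1L, k), substr(b, 1L, k)) +
    edit_dist(substr(a, la - k + 1L, la), substr(b, lb - k + 1L, lb))
  d / (2 * k)
}

#' Build consensus haplotypes from read segments
#'
#' Segments are partitioned by complete-linkage clustering on pairwise
#' edit-distance ratio (ratio > `split_threshold` forces separate groups,
#' diploid allele separation); each group of at least `min_support`
#' segments yields one consensus sequence by star alignment to a backbone
#' with per-column and per-insertion-slot majority voting.
#'
#' @param segments named character vector (names = read ids).
#' @param max_haplotypes maximum groups retained, by support (default 2).
#' @param split_threshold edit-distance ratio separating alleles (0.05).
#' @param min_support minimum segments per retained group (default 2).
#' @param max_consensus_reads at most this many segments enter the star
#'   alignment of one group (support is still counted over all members).
#' @return list of list(seq, support_reads) per haplotype, ordered by
#'   descending support then sequence.
#' @export
build_consensus <- function(segments, max_haplotypes = 2L,
                            split_threshold = 0.05, min_support = 2L,
                            max_consensus_reads = 6L) {
  n <- length(segments)
  if (n == 0L) return(list())
  if (n == 1L) groups <- list(1L)
  else {
    d <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- segment_dist(segments[[i]], segments[[j]],
                                         split_threshold)
    }
    hc <- stats::hclust(stats::as.dist(d), method = "complete")
    grp <- stats::cutree(hc, h = split_threshold)
    groups <- split(seq_len(n), grp)
  }
  groups <- groups[order(-vapply(groups, length, integer(1)))]
  groups <- groups[vapply(groups, length, integer(1)) >= min_support]
  if (length(groups) > max_haplotypes) groups <- groups[seq_len(max_haplotypes)]
  out <- list()
  for (g in groups) {
    if (length(g) < min_support) next
    segs <- segments[g]
    use <- segs
    if (length(use) > max_consensus_reads) {
      ord <- order(nchar(use))
      pick <- unique(round(seq(1, length(use), length.out = max_consensus_reads)))
      use <- use[ord][pick]
    }
    cons <- star_consensus(unname(use))
    out[[length(out) + 1L]] <- list(seq = cons, support_reads = names(segs))
  }
  if (length(out) == 0L) return(out)
  sup <- vapply(out, function(h) length(h$support_reads), integer(1))
  seqs <- vapply(out, function(h) h$seq, character(1))
  out[order(-sup, seqs)]
}

## Majority-vote consensus of near-identical sequences via star alignment
## to a backbone (the median-length sequence). Ties prefer the backbone's
## own symbol, keeping the procedure deterministic.
star_consensus <- function(seqs) {
  if (length(seqs) == 1L) return(seqs[[1]])
  ord <- order(nchar(seqs))
  backbone <- seqs[[ord[ceiling(length(seqs) / 2)]]]
  others <- seqs[-ord[ceiling(length(seqs) / 2)]]
  L <- nchar(backbone)
  bchars <- strsplit(backbone, "")[[1]]
  alpha <- c("A", "C", "G", "T", "-")
  counts <- matrix(0L, nrow = 5L, ncol = L, dimnames = list(alpha, NULL))
  ## backbone votes for itself
  counts[cbind(match(bchars, alpha), seq_len(L))] <- 1L
  ins_votes <- new.env(parent = emptyenv())  # slot -> character vector
  for (s in others) {
    pa <- align_global(s, backbone)
    p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    q <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    sel <- q != "-"
    pos <- cumsum(sel)
    ch <- p[sel]
    ix <- match(ch, alpha)
    ok <- !is.na(ix)
    ppos <- pos[sel]
    for (a in 1:5) {
      hit <- ppos[ok & ix == a]
      if (length(hit)) counts[a, ] <- counts[a, ] + tabulate(hit, nbins = L)
    }
    ## insertion slots (subject gaps): group contiguous runs
    gap <- which(!sel)
    if (length(gap)) {
      slot <- pos[gap]  # insertion after this backbone position (0 = before)
      runs <- split(gap, cumsum(c(TRUE, diff(gap) != 1L)))
      for (r in runs) {
        key <- as.character(slot[match(r[1], gap)])
        ins_votes[[key]] <- c(if (!is.null(ins_votes[[key]]))
          ins_votes[[key]] else character(0), paste(p[r], collapse = ""))
      }
    }
  }
  nvote <- length(seqs)
  pieces <- character(0)
  maj_ins <- function(slot) {
    v <- ins_votes[[as.character(slot)]]
    if (is.null(v)) return("")
    v <- c(v, rep("", nvote - length(v)))  # absent alignments vote ""
    tb <- sort(table(v), decreasing = TRUE)
    winners <- names(tb)[tb == tb[1]]
    winners[order(nchar(winners), winners)][1]
  }
  out <- character(0)
  ins0 <- maj_ins(0L)
  if (nzchar(ins0)) out <- ins0
  for (i in seq_len(L)) {
    col <- counts[, i]
    best <- max(col)
    winners <- alpha[col == best]
    base <- if (bchars[i] %in% winners) bchars[i] else winners[1]
    if (base != "-") out <- c(out, base)
    insi <- maj_ins(i)
    if (nzchar(insi)) out <- c(out, insi)
  }
  paste(out, collapse = "")
}

#' Assemble the consensus haplotypes of one cluster
#'
#' Driver combining [extract_read_segments()] and [build_consensus()];
#' attaches anchors and haplotype ids.
#'
#' @inheritParams extract_read_segments
#' @inheritParams build_consensus
#' @param min_support minimum spanning reads; below it the cluster is
#'   marked unassemblable (empty result).
#' @return list of `ConsensusHaplotype`: list(hap_id, seq, support_reads,
#'   cluster_ref, anchor, contig, sample_id).
#' @export
assemble_cluster <- function(cluster, alns, flank = 500L, contig_len = NULL,
                             max_haplotypes = 2L, split_threshold = 0.05,
                             min_support = 2L, max_consensus_reads = 6L) {
  ex <- extract_read_segments(cluster, alns, flank = flank,
                              contig_len = contig_len)
  if (length(ex$segments) < min_support) return(list())
  haps <- build_consensus(ex$segments, max_haplotypes = max_haplotypes,
                          split_threshold = split_threshold,
                          min_support = min_support,
                          max_consensus_reads = max_consensus_reads)
  lapply(seq_along(haps), function(i) {
    structure(list(
      hap_id = paste(cluster$sample_id, cluster$cluster_id, i - 1L, sep = ":"),
      seq = haps[[i]]$seq, support_reads = haps[[i]]$support_reads,
      cluster_ref = cluster$cluster_id, anchor = ex$window,
      contig = cluster$contig, sample_id = cluster$sample_id),
      class = "ConsensusHaplotype")
  })
}
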