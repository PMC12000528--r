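## Haplotype-to-reference refinement: realign each consensus haplotype to
## its reference anchor window, extract basepair-resolution breakpoints
## with microhomology / breakpoint-insertion annotation (leftmost canonical
## placement), test insertions for tandem duplication, and pair inverted
## breakend junctions into inversion events.

#' Construct an SvRecord
#'
#' @param sv_type one of DEL, INS, DUP, INV, BND.
#' @param contig,pos,end 0-based half-open coordinates (canonical leftmost).
#' @param svlen signed length (negative DEL, positive INS/DUP).
#' @param ins_seq inserted sequence for INS.
#' @param hom_len,hom_seq microhomology at the junction (leftmost placement).
#' @param hap_ref haplotype id the record derives from.
#' @param event_id shared id for multi-breakpoint events.
#' @param be1,be2 breakends: list(contig, pos, orient) with orient in
#'   left_anchor/right_anchor (which side of pos is retained sequence).
#' @param depth_support logical flag set by the depth-refinement step.
#' @return object of class `SvRecord`.
#' @export
sv_record <- function(sv_type, contig, pos, end = NA_integer_,
                      svlen = NA_integer_, ins_seq = "", hom_len = 0L,
                      hom_seq = "", hap_ref = NA_character_,
                      event_id = NA_character_, be1 = NULL, be2 = NULL,
                      depth_support = NA) {
  if (is.null(be1) && sv_type %in% c("DEL", "INS", "DUP")) {
    j2 <- if (sv_type == "INS") pos else end
    be1 <- list(contig = contig, pos = as.integer(pos), orient = "left_anchor")
    be2 <- list(contig = contig, pos = as.integer(j2), orient = "right_anchor")
  }
  bp_ins <- if (hom_len > 0L) "" else ins_seq  # annotations are exclusive
  structure(list(sv_type = sv_type, contig = contig, pos = as.integer(pos),
                 end = as.integer(end), svlen = as.integer(svlen),
                 ins_seq = ins_seq, hom_len = as.integer(hom_len),
                 hom_seq = hom_seq, bp_ins = bp_ins, hap_ref = hap_ref,
                 event_id = event_id, be1 = be1, be2 = be2,
                 depth_support = depth_support),
            class = "SvRecord")
}

#' Microhomology and canonical placement of a deletion
#'
#' Computes the interval of equivalent breakpoint placements for deleting
#' `ref_seq[del_start, del_end)` (0-based half-open): the maximal left and
#' right shifts that preserve the alternate sequence. Returns the homology
#' length, the homologous sequence at the leftmost (canonical) placement,
#' and that leftmost start.
#'
#' @param ref_seq reference window string.
#' @param del_start,del_end 0-based half-open deletion interval.
#' @return list(hom_len, hom_seq, canonical_start).
#' @export
compute_homology <- function(ref_seq, del_start, del_end) {
  n <- nchar(ref_seq)
  stopifnot(del_start >= 0, del_start < del_end, del_end <= n)
  ch <- strsplit(ref_seq, "")[[1]]
  left <- 0L
  while (del_start - 1L - left >= 0L &&
         ch[del_start - left] == ch[del_end - left]) {
    left <- left + 1L
  }
  right <- 0L
  while (del_end + right < n &&
         ch[del_start + right + 1L] == ch[del_end + right + 1L]) {
    right <- right + 1L
  }
  hom_len <- left + right
  canonical_start <- del_start - left
  hom_seq <- if (hom_len > 0L)
    substr(ref_seq, canonical_start + 1L, canonical_start + hom_len) else ""
  list(hom_len = hom_len, hom_seq = hom_seq,
       canonical_start = as.integer(canonical_start))
}

#' Microhomology and canonical placement of an insertion
#'
#' Same sliding-placement model with the inserted sequence as the mobile
#' segment: the insertion point can shift while the alternate sequence is
#' unchanged (rotating the inserted sequence accordingly).
#'
#' @param ref_seq reference window string.
#' @param pos 0-based insertion point (insertion before `ref_seq[pos]`).
#' @param ins_seq inserted sequence.
#' @return list(hom_len, hom_seq, canonical_start, canonical_ins).
#' @export
compute_ins_homology <- function(ref_seq, pos, ins_seq) {
  n <- nchar(ref_seq); m <- nchar(ins_seq)
  stopifnot(pos >= 0, pos <= n, m > 0)
  rch <- strsplit(ref_seq, "")[[1]]
  ich <- strsplit(ins_seq, "")[[1]]
  left <- 0L
  while (pos - 1L - left >= 0L &&
         rch[pos - left] == ich[m - (left %% m)]) {
    left <- left + 1L
  }
  right <- 0L
  while (pos + right < n && rch[pos + right + 1L] == ich[(right %% m) + 1L]) {
    right <- right + 1L
  }
  hom_len <- left + right
  canonical_start <- pos - left
  lm <- left %% m
  canonical_ins <- if (lm == 0L) ins_seq else
    paste0(substr(ins_seq, m - lm + 1L, m), substr(ins_seq, 1L, m - lm))
  hom_seq <- if (hom_len > 0L)
    substr(ref_seq, canonical_start + 1L,
           min(n, canonical_start + hom_len)) else ""
  list(hom_len = hom_len, hom_seq = hom_seq,
       canonical_start = as.integer(canonical_start),
       canonical_ins = canonical_ins)
}

#' Globally align a consensus haplotype to its reference anchor window
#'
#' Affine-gap global alignment (match 1, mismatch -4, gap open 6, gap
#' extend 1) so single large indels align as one gap run. Haplotypes whose
#' alignment identity in the anchor flanks falls below `min_flank_identity`
#' are flagged low-confidence and dropped (NULL returned).
#'
#' @param hap a `ConsensusHaplotype`.
#' @param ref a `ReferenceWindow` covering the haplotype anchor.
#' @param flank_check number of terminal alignment columns checked (200).
#' @param min_flank_identity identity threshold in the flanks (0.9).
#' @return list(cigar, score) or NULL when dropped.
#' @export
align_haplotype <- function(hap, ref, flank_check = 200L,
                            min_flank_identity = 0.9) {
  pa <- align_global(hap$seq, ref$seq)
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ncol <- length(p)
  k <- min(flank_check, ncol)
  fl <- mean(p[seq_len(k)] == s[seq_len(k)])
  fr <- mean(p[ncol - seq_len(k) + 1L] == s[ncol - seq_len(k) + 1L])
  if (fl < min_flank_identity || fr < min_flank_identity) {
    message("Dropping low-confidence haplotype ", hap$hap_id,
            " (flank identity ", round(min(fl, fr), 3), ")")
    return(NULL)
  }
  op <- ifelse(p == "-", "D", ifelse(s == "-", "I", "M"))
  r <- rle(op)
  list(cigar = cigar_canonical(list(op = r$values, len = r$lengths)),
       score = Biostrings::score(pa))
}

#' Extract refined SV records from a haplotype-to-reference alignment
#'
#' Each I/D run of at least `min_size` becomes a sequence-resolved INS/DEL
#' record at its canonical leftmost placement with microhomology computed
#' by [compute_homology()] / [compute_ins_homology()].
#'
#' @param alignment result of [align_haplotype()].
#' @param hap the haplotype.
#' @param ref the `ReferenceWindow` the alignment walks over.
#' @param min_size minimum |svlen| (default 50, the SV size threshold).
#' @return list of `SvRecord`.
#' @export
extract_breakpoints <- function(alignment, hap, ref, min_size = 50L) {
  cig <- alignment$cigar
  out <- list()
  roff <- 0L; q <- 0L
  for (i in seq_along(cig$op)) {
    op <- cig$op[i]; l <- cig$len[i]
    if (op == "M") { roff <- roff + l; q <- q + l }
    else if (op == "D") {
      if (l >= min_size) {
        hom <- compute_homology(ref$seq, roff, roff + l)
        pos <- ref$start + hom$canonical_start
        out[[length(out) + 1L]] <- sv_record(
          "DEL", ref$contig, pos, pos + l, -l,
          hom_len = hom$hom_len, hom_seq = hom$hom_seq, hap_ref = hap$hap_id)
      }
      roff <- roff + l
    } else if (op == "I") {
      if (l >= min_size) {
        ins <- substr(hap$seq, q + 1L, q + l)
        hom <- compute_ins_homology(ref$seq, roff, ins)
        pos <- ref$start + hom$canonical_start
        out[[length(out) + 1L]] <- sv_record(
          "INS", ref$contig, pos, pos, l, ins_seq = hom$canonical_ins,
          hom_len = hom$hom_len, hom_seq = hom$hom_seq, hap_ref = hap$hap_id)
      }
      q <- q + l
    }
  }
  out
}

#' Re-canonicalize a DEL/INS record on a wide reference window
#'
#' Canonical leftmost placement computed inside the assembly anchor window
#' can hit the window edge when the event sits in a repeat longer than the
#' flank (tandem duplications especially). This recomputes homology and
#' the canonical coordinates on a window padded by the event size plus
#' `pad_extra`, which is always wide enough to contain the full
#' equivalence interval.
#'
#' @param r an `SvRecord` (types other than DEL/INS pass through).
#' @param fasta reference FASTA path.
#' @param contig_len contig length.
#' @param pad_extra extra padding beyond |svlen| (default 500).
#' @return the re-canonicalized record.
#' @export
recanonicalize_record <- function(r, fasta, contig_len, pad_extra = 500L) {
  if (!r$sv_type %in% c("DEL", "INS")) return(r)
  pad <- abs(r$svlen) + pad_extra
  ws <- max(0L, r$pos - pad)
  we <- min(contig_len, max(r$pos, r$end, na.rm = TRUE) + pad)
  win <- fetch_reference(fasta, r$contig, ws, we)
  if (r$sv_type == "DEL") {
    h <- compute_homology(win$seq, r$pos - ws, r$end - ws)
    sv_record("DEL", r$contig, ws + h$canonical_start,
              ws + h$canonical_start + abs(r$svlen), r$svlen,
              hom_len = h$hom_len, hom_seq = h$hom_seq,
              hap_ref = r$hap_ref, event_id = r$event_id)
  } else {
    h <- compute_ins_homology(win$seq, r$pos - ws, r$ins_seq)
    sv_record("INS", r$contig, ws + h$canonical_start,
              ws + h$canonical_start, r$svlen, ins_seq = h$canonical_ins,
              hom_len = h$hom_len, hom_seq = h$hom_seq,
              hap_ref = r$hap_ref, event_id = r$event_id)
  }
}

#' Reclassify an insertion as a tandem duplication
#'
#' If the inserted sequence matches the reference segment immediately left
#' or right of the insertion point with identity at least `min_identity`
#' over at least 80% of its length, the record becomes a DUP spanning the
#' duplicated reference copy. Dispersed duplications remain INS.
#'
#' @param rec an INS `SvRecord`.
#' @param ref `ReferenceWindow` containing the insertion point and at least
#'   `svlen` bases of flank.
#' @param min_identity identity threshold (default 0.9).
#' @return the (possibly retyped) `SvRecord`.
#' @export
classify_duplication <- function(rec, ref, min_identity = 0.9) {
  if (rec$sv_type != "INS") return(rec)
  L <- rec$svlen
  off <- rec$pos - ref$start
  ident <- function(a, b) {
    if (!nzchar(a) || !nzchar(b)) return(0)
    1 - edit_dist(a, b) / max(nchar(a), nchar(b))
  }
  left_seg <- if (off - L >= 0L)
    substr(ref$seq, off - L + 1L, off) else ""
  right_seg <- if (off + L <= nchar(ref$seq))
    substr(ref$seq, off + 1L, off + L) else ""
  ## require coverage of >= 80% of the insertion length
  cov_ok <- function(seg) nchar(seg) >= 0.8 * L
  il <- if (cov_ok(left_seg)) ident(rec$ins_seq, left_seg) else 0
  ir <- if (cov_ok(right_seg)) ident(rec$ins_seq, right_seg) else 0
  if (max(il, ir) < min_identity) return(rec)
  if (il >= ir) {
    dup <- sv_record("DUP", rec$contig, rec$pos - L, rec$pos, L,
                     hom_len = rec$hom_len, hom_seq = rec$hom_seq,
                     hap_ref = rec$hap_ref)
  } else {
    dup <- sv_record("DUP", rec$contig, rec$pos, rec$pos + L, L,
                     hom_len = rec$hom_len, hom_seq = rec$hom_seq,
                     hap_ref = rec$hap_ref)
  }
  dup
}

#' Breakend record from a split-junction signature cluster
#'
#' The junction coordinates of a SPLIT_JUNCTION cluster are collapsed to
#' their most frequent value (ties to the smallest), giving a BND record
#' at basepair resolution.
#'
#' @param cluster a `SignatureCluster` whose members are SPLIT_JUNCTION.
#' @param hap_ref optional haplotype/cluster label.
#' @return an `SvRecord` of type BND, or NULL if the cluster has no
#'   junction members.
#' @export
bnd_from_junction_cluster <- function(cluster, hap_ref = NA_character_) {
  m <- cluster$members[cluster$members$kind == "SPLIT_JUNCTION", , drop = FALSE]
  if (nrow(m) == 0L) return(NULL)
  mode_val <- function(x) {
    tb <- sort(table(x), decreasing = TRUE)
    as.integer(names(tb)[tb == tb[1]][1])
  }
  pos <- mode_val(m$pos); mpos <- mode_val(m$mate_pos)
  be1 <- list(contig = cluster$contig, pos = pos, orient = m$orient[1])
  be2 <- list(contig = m$mate_contig[1], pos = mpos, orient = m$mate_orient[1])
  ## canonical ordering: smallest contig/pos first
  if (be2$contig < be1$contig ||
      (be2$contig == be1$contig && be2$pos < be1$pos)) {
    tmp <- be1; be1 <- be2; be2 <- tmp
  }
  sv_record("BND", be1$contig, be1$pos, svlen = NA_integer_,
            hap_ref = hap_ref, be1 = be1, be2 = be2)
}

#' Pair inverted breakends into inversion events
#'
#' Two intra-contig BND records with inverted-orientation breakends (one
#' junction retaining sequence left of both breakends, the other right of
#' both) whose coordinates nest within `pair_tol` are joined under one
#' event id and summarized by a symbolic INV record; the component BNDs are
#' retained and tagged with the same event id.
#'
#' @param bnds list of BND `SvRecord`s from one sample.
#' @param max_span maximum inversion span considered (default 2 Mb).
#' @param pair_tol coordinate tolerance for pairing junctions (default 1000).
#' @param min_size minimum inversion span (default 50).
#' @return list of `SvRecord`: INV events followed by all input BNDs.
#' @export
pair_inversion <- function(bnds, max_span = 2e6, pair_tol = 1000L,
                           min_size = 50L) {
  orient_sig <- function(b) paste0(substr(b$be1$orient, 1, 1),
                                   substr(b$be2$orient, 1, 1))
  intra <- vapply(bnds, function(b) b$be1$contig == b$be2$contig, logical(1))
  sig <- vapply(bnds, orient_sig, character(1))
  ll <- which(intra & sig == "ll")
  rr <- which(intra & sig == "rr")
  invs <- list()
  used_rr <- integer(0)
  for (i in ll) {
    b1 <- bnds[[i]]
    L1 <- min(b1$be1$pos, b1$be2$pos); R1 <- max(b1$be1$pos, b1$be2$pos)
    best <- NA_integer_; best_d <- Inf
    for (j in setdiff(rr, used_rr)) {
      b2 <- bnds[[j]]
      if (b2$be1$contig != b1$be1$contig) next
      L2 <- min(b2$be1$pos, b2$be2$pos); R2 <- max(b2$be1$pos, b2$be2$pos)
      if (abs(L1 - L2) > pair_tol || abs(R1 - R2) > pair_tol) next
      if (max(R1, R2) - min(L1, L2) > max_span) next
      d <- abs(L1 - L2) + abs(R1 - R2)
      if (d < best_d) { best <- j; best_d <- d }
    }
    if (!is.na(best)) {
      b2 <- bnds[[best]]
      L2 <- min(b2$be1$pos, b2$be2$pos); R2 <- max(b2$be1$pos, b2$be2$pos)
      pos <- min(L1, L2); end <- max(R1, R2)
      if (end - pos < min_size) next
      ev <- paste0("INV_", b1$be1$contig, "_", pos)
      bnds[[i]]$event_id <- ev
      bnds[[best]]$event_id <- ev
      used_rr <- c(used_rr, best)
      invs[[length(invs) + 1L]] <- sv_record(
        "INV", b1$be1$contig, pos, end, end - pos, event_id = ev,
        hap_ref = b1$hap_ref,
        be1 = list(contig = b1$be1$contig, pos = pos, orient = "left_anchor"),
        be2 = list(contig = b1$be1$contig, pos = end, orient = "right_anchor"))
    }
  }
  c(invs, bnds)
}
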