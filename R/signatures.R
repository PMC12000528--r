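## SV-associated alignment signatures: large CIGAR indels, split-read
## junctions and long terminal soft clips. Signatures are kept in a flat
## data.frame so clustering can vectorize over them.

SIG_COLS <- c("kind", "contig", "pos", "size", "ins_seq", "read_id",
              "sample_id", "orient", "mate_contig", "mate_pos", "mate_orient")

empty_signatures <- function() {
  data.frame(kind = character(0), contig = character(0), pos = integer(0),
             size = integer(0), ins_seq = character(0), read_id = character(0),
             sample_id = character(0), orient = character(0),
             mate_contig = character(0), mate_pos = integer(0),
             mate_orient = character(0), stringsAsFactors = FALSE)
}

sig_row <- function(kind, contig, pos, size, ins_seq, read_id, sample_id,
                    orient = NA_character_, mate_contig = NA_character_,
                    mate_pos = NA_integer_, mate_orient = NA_character_) {
  data.frame(kind = kind, contig = contig, pos = as.integer(pos),
             size = as.integer(size), ins_seq = ins_seq, read_id = read_id,
             sample_id = sample_id, orient = orient,
             mate_contig = mate_contig, mate_pos = as.integer(mate_pos),
             mate_orient = mate_orient, stringsAsFactors = FALSE)
}

#' Extract SV signatures from one alignment record
#'
#' Walks the CIGAR and emits one INDEL_DEL/INDEL_INS signature per I/D run
#' of at least `min_signature_size` bases (positioned at the walked
#' reference coordinate; for deletions the first deleted base) and one
#' SOFTCLIP signature per terminal S run of at least `min_clip_size` bases.
#' Split-read junction signatures are derived separately by
#' [split_junctions()] because they need all segments of a read.
#'
#' @param aln a `ReadAlignment`.
#' @param min_signature_size minimum indel run length (default 35, below the
#'   50 bp SV threshold so fragmented events still seed clusters).
#' @param min_clip_size minimum soft-clip length (default 200).
#' @return data.frame of signatures sorted by position.
#' @export
extract_signatures <- function(aln, min_signature_size = 35L,
                               min_clip_size = 200L) {
  cig <- aln$cigar
  out <- list()
  r <- aln$start; q <- 0L
  for (i in seq_along(cig$op)) {
    op <- cig$op[i]; l <- cig$len[i]
    if (op %in% c("M", "=", "X")) {
      r <- r + l; q <- q + l
    } else if (op == "D") {
      if (l >= min_signature_size) {
        out[[length(out) + 1L]] <- sig_row("INDEL_DEL", aln$contig, r, l,
                                           NA_character_, aln$read_id,
                                           aln$sample_id)
      }
      r <- r + l
    } else if (op == "I") {
      if (l >= min_signature_size) {
        ins <- if (nzchar(aln$seq)) substr(aln$seq, q + 1L, q + l) else
          NA_character_
        out[[length(out) + 1L]] <- sig_row("INDEL_INS", aln$contig, r, l,
                                           ins, aln$read_id, aln$sample_id)
      }
      q <- q + l
    } else if (op == "S") {
      if (l >= min_clip_size) {
        ## clip anchors at the adjacent aligned base
        pos <- if (i == 1L) r else r
        out[[length(out) + 1L]] <- sig_row("SOFTCLIP", aln$contig, pos, l,
                                           NA_character_, aln$read_id,
                                           aln$sample_id,
                                           orient = if (i == 1L)
                                             "right_anchor" else "left_anchor")
      }
      q <- q + l
    }
  }
  if (length(out) == 0L) return(empty_signatures())
  df <- do.call(rbind, out)
  df[order(df$pos), , drop = FALSE]
}

## Read-space interval of one alignment record (original read orientation).
read_space_interval <- function(aln) {
  cig <- aln$cigar
  lead <- if (length(cig$op) && cig$op[1] %in% c("S", "H")) cig$len[1] else 0L
  trail <- if (length(cig$op) > 1L &&
               cig$op[length(cig$op)] %in% c("S", "H"))
    cig$len[length(cig$op)] else 0L
  qlen <- cigar_query_len(cig) +
    sum(cig$len[cig$op == "H"])  # full read length incl. hard clips
  aligned <- qlen - lead - trail
  if (aln$is_reverse) {
    c(start = qlen - lead - aligned, end = qlen - lead)
  } else {
    c(start = lead, end = lead + aligned)
  }
}

#' Derive split-read junction signatures from the segments of one read
#'
#' Segments are ordered along the read; each adjacent pair yields one
#' SPLIT_JUNCTION signature with breakend orientations derived from strand
#' and segment order: a `left_anchor` breakend retains reference sequence to
#' the left of `pos`, a `right_anchor` breakend to the right.
#'
#' @param alns all alignment records (primary + supplementary) of one read.
#' @return data.frame of SPLIT_JUNCTION signatures (possibly empty).
#' @export
split_junctions <- function(alns) {
  if (length(alns) < 2L) return(empty_signatures())
  ivs <- t(vapply(alns, read_space_interval, c(start = 0, end = 0)))
  ord <- order(ivs[, "start"])
  alns <- alns[ord]
  out <- list()
  for (i in seq_len(length(alns) - 1L)) {
    a <- alns[[i]]; b <- alns[[i + 1L]]
    ## breakend of segment a at its read-space end
    if (!a$is_reverse) {
      be1 <- list(contig = a$contig, pos = aln_ref_end(a), orient = "left_anchor")
    } else {
      be1 <- list(contig = a$contig, pos = a$start, orient = "right_anchor")
    }
    ## breakend of segment b at its read-space start
    if (!b$is_reverse) {
      be2 <- list(contig = b$contig, pos = b$start, orient = "right_anchor")
    } else {
      be2 <- list(contig = b$contig, pos = aln_ref_end(b), orient = "left_anchor")
    }
    out[[length(out) + 1L]] <- sig_row(
      "SPLIT_JUNCTION", be1$contig, be1$pos, 0L, NA_character_,
      a$read_id, a$sample_id, orient = be1$orient,
      mate_contig = be2$contig, mate_pos = be2$pos, mate_orient = be2$orient)
  }
  df <- do.call(rbind, out)
  df[order(df$pos), , drop = FALSE]
}

#' Merge nearby same-kind indel signatures of one read
#'
#' Aligners fragment one SV into nearby CIGAR runs; same-kind INDEL
#' signatures separated by at most `max_gap` reference bases are merged
#' into one signature with summed size (insertion sequences concatenated).
#'
#' @param sigs position-sorted signatures from a single read.
#' @param max_gap maximum reference gap between merged runs (default 50).
#' @return merged signature data.frame.
#' @export
merge_adjacent_indels <- function(sigs, max_gap = 50L) {
  if (nrow(sigs) < 2L) return(sigs)
  merge_kind <- function(sub) {
    if (nrow(sub) < 2L) return(sub)
    sub <- sub[order(sub$pos), , drop = FALSE]
    keep <- rep(TRUE, nrow(sub))
    cur <- 1L
    for (j in 2L:nrow(sub)) {
      end_cur <- sub$pos[cur] +
        if (sub$kind[cur] == "INDEL_DEL") sub$size[cur] else 0L
      gap <- sub$pos[j] - end_cur
      if (sub$contig[cur] == sub$contig[j] && gap <= max_gap) {
        sub$size[cur] <- sub$size[cur] + sub$size[j]
        if (sub$kind[cur] == "INDEL_INS") {
          a <- sub$ins_seq[cur]; b <- sub$ins_seq[j]
          sub$ins_seq[cur] <- if (is.na(a) || is.na(b)) NA_character_ else
            paste0(a, b)
        }
        keep[j] <- FALSE
      } else {
        cur <- j
      }
    }
    sub[keep, , drop = FALSE]
  }
  is_indel <- sigs$kind %in% c("INDEL_DEL", "INDEL_INS")
  parts <- c(lapply(split(sigs[is_indel, , drop = FALSE],
                          sigs$kind[is_indel]), merge_kind),
             list(sigs[!is_indel, , drop = FALSE]))
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out[order(out$pos), , drop = FALSE]
}

#' Extract all signatures for a set of alignments
#'
#' Convenience driver: per-read CIGAR signatures (with adjacent-indel
#' merging) plus split-read junctions.
#' @inheritParams extract_signatures
#' @param alns list of `ReadAlignment` records.
#' @param max_gap see [merge_adjacent_indels()].
#' @return combined signature data.frame sorted by (contig, pos).
#' @export
scan_signatures <- function(alns, min_signature_size = 35L,
                            min_clip_size = 200L, max_gap = 50L) {
  by_read <- split(seq_along(alns),
                   vapply(alns, function(a) a$read_id, character(1)))
  out <- vector("list", length(by_read))
  k <- 0L
  for (idx in by_read) {
    segs <- alns[idx]
    sig <- do.call(rbind, c(list(empty_signatures()),
                            lapply(segs, extract_signatures,
                                   min_signature_size = min_signature_size,
                                   min_clip_size = min_clip_size)))
    sig <- sig[order(sig$pos), , drop = FALSE]
    sig <- merge_adjacent_indels(sig, max_gap = max_gap)
    sj <- split_junctions(segs)
    k <- k + 1L
    out[[k]] <- rbind(sig, sj)
  }
  df <- do.call(rbind, c(list(empty_signatures()), out))
  df[order(df$contig, df$pos), , drop = FALSE]
}
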