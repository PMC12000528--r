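## Cross-sample haplotype merging, relative-read-support genotyping with a
## binomial-mixture quality model, and local phasing of overlapping
## heterozygous calls.

#' Genotype model parameters
#'
#' @param epsilon per-read allele mis-support probability (default 0.05).
#' @param min_score_margin alignment-score margin (edit-distance units)
#'   required to assign a read to an allele (default 10).
#' @param flank_score flank used for read-vs-allele scoring windows (300).
#' @param max_direct loci with reference footprint and length change up to
#'   this size are scored on one full-span window; larger events are scored
#'   on junction-local windows (default 2000).
#' @return list of class `GenotypeModelParams`.
#' @export
genotype_params <- function(epsilon = 0.05, min_score_margin = 10L,
                            flank_score = 300L, max_direct = 2000L) {
  stopifnot(epsilon > 0, epsilon < 0.5)
  structure(list(epsilon = epsilon, min_score_margin = min_score_margin,
                 flank_score = flank_score, max_direct = max_direct),
            class = "GenotypeModelParams")
}

locus_footprint <- function(records) {
  pos <- vapply(records, function(r) r$pos, integer(1))
  end <- vapply(records, function(r)
    if (is.na(r$end)) r$pos else max(r$pos, r$end), integer(1))
  c(start = min(pos), end = max(end))
}

#' Merge consensus haplotypes across samples into SV loci
#'
#' Haplotypes whose anchors lie within `max_merge_dist` of each other are
#' compared by sequence: an edit-distance ratio of at most
#' (1 - `merge_similarity`) makes them the same allele (support pooled);
#' otherwise they are distinct alleles of one locus. Allele indices are
#' assigned by descending total support, ties by sequence order. At most
#' two alleles per sample contribute (extras dropped by support).
#'
#' @param haps list of `ConsensusHaplotype`, each carrying a `records`
#'   element with its refined `SvRecord`s.
#' @param max_merge_dist anchor-distance threshold (default 500).
#' @param merge_similarity sequence similarity treated as identical (0.99).
#' @return list of `SvLocus`: list(locus_id, contig, span, alleles,
#'   genotypes); each allele is list(seq, records, support) where support
#'   is a per-sample list of read ids.
#' @export
merge_haplotypes <- function(haps, max_merge_dist = 500L,
                             merge_similarity = 0.99) {
  haps <- Filter(function(h) length(h$records) > 0L, haps)
  if (length(haps) == 0L) return(list())
  n <- length(haps)
  contig <- vapply(haps, function(h) h$contig, character(1))
  fp <- t(vapply(haps, function(h) locus_footprint(h$records),
                 c(start = 0L, end = 0L)))
  parent <- uf_new(n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (contig[i] != contig[j]) next
    gap <- max(fp[i, 1], fp[j, 1]) - min(fp[i, 2], fp[j, 2])
    if (gap <= max_merge_dist) parent <- uf_union(parent, i, j)
  }
  comp <- uf_components(parent)
  loci <- list()
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    sub <- haps[idx]
    ## allele deduplication by sequence similarity (complete linkage)
    m <- length(sub)
    ap <- uf_new(m)
    if (m > 1L) {
      for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
        a <- sub[[i]]$seq; b <- sub[[j]]$seq
        ml <- (nchar(a) + nchar(b)) / 2
        if (abs(nchar(a) - nchar(b)) / ml > (1 - merge_similarity)) next
        if (edit_dist(a, b) / ml <= (1 - merge_similarity)) {
          ap <- uf_union(ap, i, j)
        }
      }
    }
    acomp <- uf_components(ap)
    alleles <- list()
    for (aid in unique(acomp)) {
      members <- sub[acomp == aid]
      support <- list()
      for (h in members) {
        support[[h$sample_id]] <- unique(c(support[[h$sample_id]],
                                           h$support_reads))
      }
      tot <- sum(vapply(support, length, integer(1)))
      rep_h <- members[[order(-vapply(members, function(h)
        length(h$support_reads), integer(1)),
        vapply(members, function(h) h$seq, character(1)))[1]]]
      alleles[[length(alleles) + 1L]] <- list(
        seq = rep_h$seq, records = rep_h$records, support = support,
        total_support = tot, hap_ids = vapply(members, function(h) h$hap_id,
                                              character(1)))
    }
    alleles <- alleles[order(-vapply(alleles, function(a) a$total_support,
                                     integer(1)),
                             vapply(alleles, function(a) a$seq, character(1)))]
    ## cap two alleles per sample
    if (length(alleles) > 2L) {
      for (s in unique(unlist(lapply(alleles, function(a) names(a$support))))) {
        has <- which(vapply(alleles, function(a) !is.null(a$support[[s]]),
                            logical(1)))
        if (length(has) > 2L) {
          drop <- has[-seq_len(2L)]
          for (d in drop) alleles[[d]]$support[[s]] <- NULL
          message("Locus on ", contig[idx[1]], ": sample ", s,
                  " contributed >2 alleles; keeping top 2 by support")
        }
      }
      alleles <- Filter(function(a) length(a$support) > 0L, alleles)
    }
    recs <- do.call(c, lapply(alleles, function(a) a$records))
    loci[[length(loci) + 1L]] <- structure(list(
      locus_id = NA_character_, contig = contig[idx[1]],
      span = locus_footprint(recs), alleles = alleles,
      genotypes = list()), class = "SvLocus")
  }
  order_loci(loci)
}

order_loci <- function(loci) {
  if (length(loci) == 0L) return(loci)
  ord <- order(vapply(loci, function(l) l$contig, character(1)),
               vapply(loci, function(l) l$span[["start"]], integer(1)))
  loci <- loci[ord]
  for (i in seq_along(loci)) {
    loci[[i]]$locus_id <- sprintf("locus_%04d", i - 1L)
  }
  loci
}

#' Merge coordinate-defined loci (inversions) across samples
#'
#' Inversion events carry no assembled alternate sequence, so cross-sample
#' merging compares coordinates: INV records whose pos and end agree within
#' `max_merge_dist` collapse to one locus with a single alternate allele.
#'
#' @param inv_by_sample named list (sample -> list of INV `SvRecord`).
#' @param support_by_sample named list (sample -> list mapping event_id to
#'   supporting read ids).
#' @param max_merge_dist coordinate tolerance (default 500).
#' @return list of `SvLocus` with coordinate alleles.
#' @export
merge_inv_loci <- function(inv_by_sample, support_by_sample = list(),
                           max_merge_dist = 500L) {
  recs <- list(); samples <- character(0)
  for (s in names(inv_by_sample)) for (r in inv_by_sample[[s]]) {
    recs[[length(recs) + 1L]] <- r
    samples <- c(samples, s)
  }
  if (length(recs) == 0L) return(list())
  n <- length(recs)
  parent <- uf_new(n)
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (recs[[i]]$contig != recs[[j]]$contig) next
    if (abs(recs[[i]]$pos - recs[[j]]$pos) <= max_merge_dist &&
        abs(recs[[i]]$end - recs[[j]]$end) <= max_merge_dist) {
      parent <- uf_union(parent, i, j)
    }
  }
  comp <- uf_components(parent)
  loci <- list()
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    rep_r <- recs[[idx[1]]]
    support <- list()
    for (k in idx) {
      s <- samples[k]
      ev <- recs[[k]]$event_id
      rd <- if (!is.null(support_by_sample[[s]]) && !is.na(ev))
        support_by_sample[[s]][[ev]] else NULL
      support[[s]] <- unique(c(support[[s]], rd))
    }
    allele <- list(seq = NULL, records = list(rep_r), support = support,
                   total_support = sum(vapply(support, length, integer(1))),
                   hap_ids = character(0))
    loci[[length(loci) + 1L]] <- structure(list(
      locus_id = NA_character_, contig = rep_r$contig,
      span = c(start = rep_r$pos, end = rep_r$end),
      alleles = list(allele), genotypes = list()), class = "SvLocus")
  }
  loci
}

## Apply a set of SvRecords to a reference window string, producing the
## alternate-allele sequence over the same window.
apply_records_to_window <- function(refseq, wstart, records) {
  ords <- order(-vapply(records, function(r) r$pos, integer(1)))
  s <- refseq
  for (r in records[ords]) {
    p <- r$pos - wstart
    if (r$sv_type == "DEL") {
      e <- r$end - wstart
      s <- paste0(substr(s, 1L, p), substr(s, e + 1L, nchar(s)))
    } else if (r$sv_type == "INS") {
      s <- paste0(substr(s, 1L, p), r$ins_seq, substr(s, p + 1L, nchar(s)))
    } else if (r$sv_type == "DUP") {
      e <- r$end - wstart
      copy <- substr(s, p + 1L, e)
      s <- paste0(substr(s, 1L, e), copy, substr(s, e + 1L, nchar(s)))
    } else if (r$sv_type == "INV") {
      e <- r$end - wstart
      s <- paste0(substr(s, 1L, p), revcomp(substr(s, p + 1L, e)),
                  substr(s, e + 1L, nchar(s)))
    }
  }
  s
}

#' Build the per-allele scoring windows of a locus
#'
#' Small loci are scored on one full-span window; large events are scored
#' on junction-local windows extracted from the read in query space, which
#' keeps scoring cost independent of event size.
#'
#' @param locus an `SvLocus`.
#' @param ref `ReferenceWindow` covering span +/- (flank_score + max event
#'   size) as needed.
#' @param params `GenotypeModelParams`.
#' @return list of windows: each list(mode = "fwd"/"rev", anchor, width,
#'   alleles = character vector of per-allele window sequences, ref first).
#' @keywords internal
build_scoring_windows <- function(locus, ref, params) {
  w <- params$flank_score
  S <- locus$span[["start"]]; E <- locus$span[["end"]]
  k <- length(locus$alleles)
  len_change <- max(vapply(locus$alleles, function(a)
    sum(abs(vapply(a$records, function(r)
      if (is.na(r$svlen)) 0L else r$svlen, integer(1)))), integer(1)))
  slice <- function(s0, e0) {
    substr(ref$seq, s0 - ref$start + 1L, e0 - ref$start)
  }
  types <- unique(unlist(lapply(locus$alleles, function(a)
    vapply(a$records, function(r) r$sv_type, character(1)))))
  ## split-aligned events (INV/BND) can never be covered by one read
  ## record end-to-end, so they always use junction windows
  if (all(types %in% c("DEL", "INS", "DUP")) &&
      (E - S) <= params$max_direct && len_change <= params$max_direct) {
    ws <- S - w; we <- E + w
    refseq <- slice(ws, we)
    alt <- vapply(locus$alleles, function(a)
      apply_records_to_window(refseq, ws, a$records), character(1))
    return(list(list(mode = "fwd", anchor = ws, width = NA_integer_,
                     end_anchor = we, alleles = c(refseq, alt))))
  }
  ## junction windows per locus (union over alleles; alleles evaluated on
  ## their own junction sequence). One window set shared: use the first
  ## record of each allele -- loci here are single-event by construction.
  wins <- list()
  add_fwd <- function(anchor, seqs) {
    wins[[length(wins) + 1L]] <<- list(mode = "fwd", anchor = anchor,
                                       width = 2L * w, alleles = seqs)
  }
  add_rev <- function(anchor, seqs) {
    wins[[length(wins) + 1L]] <<- list(mode = "rev", anchor = anchor,
                                       width = 2L * w, alleles = seqs)
  }
  alt_fwd <- character(k); alt_rev <- character(k)
  r0 <- locus$alleles[[1]]$records[[1]]
  type <- r0$sv_type
  if (type == "DEL") {
    ref_w <- slice(S - w, S + w)
    alt <- vapply(locus$alleles, function(a) {
      r <- a$records[[1]]
      paste0(slice(r$pos - w, r$pos), slice(r$end, r$end + w))
    }, character(1))
    add_fwd(S - w, c(ref_w, alt))
  } else if (type == "INS") {
    ref_w <- slice(S - w, S + w)
    alt <- vapply(locus$alleles, function(a) {
      r <- a$records[[1]]
      paste0(slice(r$pos - w, r$pos), substr(r$ins_seq, 1L, w))
    }, character(1))
    add_fwd(S - w, c(ref_w, alt))
    ref_w2 <- slice(S - w, S + w)
    alt2 <- vapply(locus$alleles, function(a) {
      r <- a$records[[1]]
      m <- nchar(r$ins_seq)
      paste0(substr(r$ins_seq, m - w + 1L, m), slice(r$pos, r$pos + w))
    }, character(1))
    add_rev(S + w, c(ref_w2, alt2))
  } else if (type == "DUP") {
    ref_w <- slice(E - w, E + w)
    alt <- vapply(locus$alleles, function(a) {
      r <- a$records[[1]]
      paste0(slice(r$end - w, r$end), slice(r$pos, r$pos + w))
    }, character(1))
    add_fwd(E - w, c(ref_w, alt))
  } else if (type == "INV") {
    ref_l <- slice(S - w, S + w)
    alt_l <- vapply(locus$alleles, function(a) {
      r <- a$records[[1]]
      paste0(slice(r$pos - w, r$pos), revcomp(slice(r$end - w, r$end)))
    }, character(1))
    add_fwd(S - w, c(ref_l, alt_l))
    ref_r <- slice(E - w, E + w)
    alt_r <- vapply(locus$alleles, function(a) {
      r <- a$records[[1]]
      paste0(revcomp(slice(r$pos, r$pos + w)), slice(r$end, r$end + w))
    }, character(1))
    add_rev(E + w, c(ref_r, alt_r))
  } else {
    ## BND and other types: fall back to a window at the first breakend
    ref_w <- slice(S - w, S + w)
    add_fwd(S - w, c(ref_w, rep(ref_w, k)))
  }
  wins
}

## Query-space segment of a read at a scoring window; NA when the read does
## not cover the window anchor with enough sequence.
read_window_segment <- function(read_alns, win) {
  for (a in read_alns) {
    if (!nzchar(a$seq)) next
    q <- query_pos_at_ref(a$cigar, a$start, win$anchor)
    if (is.na(q)) next
    if (win$mode == "fwd") {
      wd <- if (is.na(win$width)) {
        qe <- query_pos_at_ref(a$cigar, a$start, win$end_anchor)
        if (is.na(qe)) {
          if (aln_ref_end(a) == win$end_anchor) {
            qe <- cigar_query_len(a$cigar) -
              (if (a$cigar$op[length(a$cigar$op)] == "S")
                a$cigar$len[length(a$cigar$op)] else 0L)
          } else next
        }
        return(substr(a$seq, q + 1L, qe))
      } else win$width
      if (q + wd > nchar(a$seq)) next
      return(substr(a$seq, q + 1L, q + wd))
    } else {
      if (q < win$width) next
      return(substr(a$seq, q - win$width + 1L, q))
    }
  }
  NA_character_
}

#' Assign a read to a locus allele by relative alignment support
#'
#' The read's query segments over the locus scoring windows are compared to
#' each allele's window sequences by edit distance; the read is assigned to
#' the best-scoring allele when its margin over the runner-up is at least
#' `min_score_margin`, otherwise left unassigned. A read votes through
#' every window it spans with both flanks (for junction windows of large
#' events a single junction suffices — each junction is independently
#' discriminative, and requiring the full event span would bias allele
#' depths against long alternates); reads spanning no window are
#' unassigned.
#'
#' @param read_alns all alignment records of one read.
#' @param windows result of [build_scoring_windows()].
#' @param params `GenotypeModelParams`.
#' @return 0-based allele index (0 = reference) or NA.
#' @export
score_read_vs_alleles <- function(read_alns, windows, params) {
  k <- length(windows[[1]]$alleles)
  total <- numeric(k)
  used <- 0L
  for (win in windows) {
    seg <- read_window_segment(read_alns, win)
    if (is.na(seg)) next
    used <- used + 1L
    total <- total + vapply(win$alleles, function(al)
      as.numeric(edit_dist(seg, al)), numeric(1))
  }
  if (used == 0L) return(NA_integer_)
  ord <- order(total)
  if (k > 1L && total[ord[2]] - total[ord[1]] < params$min_score_margin) {
    return(NA_integer_)
  }
  ord[1] - 1L
}

#' Genotype a locus from per-allele read counts
#'
#' Binomial-mixture model: a read drawn from haplotype h supports allele h
#' with probability 1 - epsilon and any other allele with probability
#' epsilon/(K-1) (K alleles including reference); a diploid genotype mixes
#' its two haplotypes equally. The posterior over all diploid genotypes
#' under a uniform prior gives the call and the phred-scaled GQ
#' floor(-10 log10(1 - posterior)), capped at 999.
#'
#' @param ad integer vector of per-allele supporting read counts, index 1 =
#'   reference allele 0.
#' @param params `GenotypeModelParams`.
#' @return list(gt = unordered pair of allele indices or NULL for ./., gq,
#'   posterior, posteriors = named vector).
#' @export
genotype_locus <- function(ad, params = genotype_params()) {
  K <- length(ad)
  eps <- params$epsilon
  if (sum(ad) == 0L) {
    return(list(gt = NULL, gq = 0L, posterior = NA_real_,
                posteriors = stats::setNames(numeric(0), character(0))))
  }
  e_prob <- function(x, h) if (x == h) 1 - eps else eps / (K - 1)
  gts <- list()
  for (a in 0:(K - 1)) for (b in a:(K - 1)) gts[[length(gts) + 1L]] <- c(a, b)
  loglik <- vapply(gts, function(g) {
    sum(vapply(seq_len(K), function(x) {
      p <- 0.5 * e_prob(x - 1L, g[1]) + 0.5 * e_prob(x - 1L, g[2])
      if (ad[x] == 0L) 0 else ad[x] * log(p)
    }, numeric(1)))
  }, numeric(1))
  post <- exp(loglik - max(loglik))
  post <- post / sum(post)
  names(post) <- vapply(gts, function(g) paste(g, collapse = "/"), character(1))
  best <- which.max(post)
  list(gt = gts[[best]], gq = phred_floor(post[best]),
       posterior = unname(post[best]), posteriors = post)
}

#' Phase overlapping heterozygous loci of one sample
#'
#' Two heterozygous loci are phased when they share read-to-allele
#' assignments (or derive from the same assembled haplotype pair): reads
#' supporting both alternate alleles are cis evidence; reads supporting
#' one alternate and the other reference are trans evidence. Conflicting
#' evidence (both cis and trans observed) leaves the pair unphased. Phased
#' genotypes receive a common phase set id (position of the leftmost locus
#' in the set) and an ordered genotype.
#'
#' @param loci position-sorted list of `SvLocus` with genotypes filled.
#' @param sample_id sample to phase.
#' @param max_phase_dist maximum span gap between phased loci (default
#'   2000).
#' @return the updated loci list.
#' @export
phase_overlapping <- function(loci, sample_id, max_phase_dist = 2000L) {
  is_het <- function(l) {
    g <- l$genotypes[[sample_id]]
    !is.null(g) && !is.null(g$gt) && g$gt[1] != g$gt[2] && 0L %in% g$gt
  }
  idx <- which(vapply(loci, is_het, logical(1)))
  if (length(idx) < 2L) return(loci)
  for (t in seq_len(length(idx) - 1L)) {
    i <- idx[t]; j <- idx[t + 1L]
    if (loci[[i]]$contig != loci[[j]]$contig) next
    gap <- loci[[j]]$span[["start"]] - loci[[i]]$span[["end"]]
    if (gap > max_phase_dist) next
    gi <- loci[[i]]$genotypes[[sample_id]]
    gj <- loci[[j]]$genotypes[[sample_id]]
    ai <- gi$assignments; aj <- gj$assignments
    shared <- intersect(names(ai)[!is.na(ai)], names(aj)[!is.na(aj)])
    alt_i <- max(gi$gt); alt_j <- max(gj$gt)
    cis <- sum(ai[shared] == alt_i & aj[shared] == alt_j)
    trans <- sum((ai[shared] == alt_i & aj[shared] == 0L) |
                   (ai[shared] == 0L & aj[shared] == alt_j))
    ## same assembled haplotype pair also implies cis
    same_hap <- length(intersect(
      unlist(lapply(loci[[i]]$alleles, function(a) a$hap_ids)),
      unlist(lapply(loci[[j]]$alleles, function(a) a$hap_ids)))) > 0L
    if (same_hap && cis == 0L && trans == 0L) cis <- 1L
    if ((cis > 0L && trans > 0L) || (cis == 0L && trans == 0L)) {
      if (cis > 0L && trans > 0L) {
        message("Conflicting phase evidence between ", loci[[i]]$locus_id,
                " and ", loci[[j]]$locus_id, " in ", sample_id,
                "; left unphased")
      }
      next
    }
    if (!isTRUE(gi$phased)) {
      gi$phased <- TRUE
      gi$ps <- loci[[i]]$span[["start"]]
      gi$gt_ordered <- c(alt_i, 0L)  # alt on haplotype 1 by convention
    }
    gj$phased <- TRUE
    gj$ps <- gi$ps
    alt_on_h1 <- gi$gt_ordered[1] != 0L
    gj$gt_ordered <- if ((cis > 0L) == alt_on_h1) c(alt_j, 0L) else c(0L, alt_j)
    loci[[i]]$genotypes[[sample_id]] <- gi
    loci[[j]]$genotypes[[sample_id]] <- gj
  }
  loci
}
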