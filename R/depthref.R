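## Binned read-depth evidence for unbalanced (DEL/DUP) candidates.

#' Build a binned depth track for one contig
#'
#' Each bin's value is the total number of aligned reference-consuming
#' bases (M/=/X) of primary reads overlapping the bin, divided by
#' `bin_size`.
#'
#' @param alns list of `ReadAlignment` from one sample and contig.
#' @param contig_len contig length in bp.
#' @param bin_size bin width in bp (default 1000).
#' @return list of class `DepthTrack`: list(contig, bin_size, bins).
#' @export
build_depth_track <- function(alns, contig_len, bin_size = 1000L) {
  contig <- if (length(alns)) alns[[1]]$contig else NA_character_
  n_bins <- ceiling(contig_len / bin_size)
  cov <- S4Vectors::Rle(0L, contig_len)
  starts <- integer(0); ends <- integer(0)
  for (a in alns) {
    if (!is.na(a$supplementary_of)) next  # primary records only
    blocks <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      cigar_string(a$cigar), ops = c("M", "=", "X"), pos = a$start + 1L)[[1]]
    starts <- c(starts, IRanges::start(blocks))
    ends <- c(ends, IRanges::end(blocks))
  }
  if (length(starts)) {
    ends <- pmin(ends, contig_len)
    keep <- starts <= ends
    cov <- IRanges::coverage(IRanges::IRanges(starts[keep], ends[keep]),
                             width = contig_len)
  }
  bs <- (seq_len(n_bins) - 1L) * bin_size + 1L
  be <- pmin(seq_len(n_bins) * bin_size, contig_len)
  sums <- vapply(IRanges::Views(cov, bs, be), sum, numeric(1))
  structure(list(contig = contig, bin_size = as.integer(bin_size),
                 bins = sums / bin_size),
            class = "DepthTrack")
}

#' Depth ratio of an event interval against its flanks
#'
#' Mean depth of the bins fully inside the event divided by the mean depth
#' of `flank` bp of bins on each side (event excluded). NA when the event
#' holds no full bin or the flank mean is zero.
#'
#' @param track a `DepthTrack`.
#' @param event c(start, end), 0-based half-open.
#' @param flank flank width in bp per side (default 5000).
#' @return ratio (numeric) or NA.
#' @export
depth_ratio <- function(track, event, flank = 5000L) {
  bs <- track$bin_size
  n <- length(track$bins)
  bin_start <- (seq_len(n) - 1L) * bs       # 0-based bin intervals
  bin_end <- bin_start + bs
  inside <- bin_start >= event[1] & bin_end <= event[2]
  if (!any(inside)) return(NA_real_)        # event smaller than one bin
  lf <- bin_end <= event[1] & bin_start >= event[1] - flank
  rf <- bin_start >= event[2] & bin_end <= event[2] + flank
  fl <- c(track$bins[lf], track$bins[rf])
  if (length(fl) == 0L || mean(fl) == 0) return(NA_real_)
  mean(track$bins[inside]) / mean(fl)
}

#' Corroborate or reclassify an unbalanced candidate with depth evidence
#'
#' The expected depth ratio is 1 - 0.5 x (alt dosage) for DEL and
#' 1 + 0.5 x (alt dosage) for DUP. A ratio within `tol` of its own
#' expectation sets `depth_support = TRUE`; a candidate failing its own
#' expectation but matching the opposite type's is flipped and flagged.
#'
#' @param record a DEL or DUP `SvRecord`.
#' @param dosage number of alternate alleles in the genotype (1 het, 2 hom).
#' @param ratio observed depth ratio (see [depth_ratio()]).
#' @param tol tolerance on the ratio (default 0.25).
#' @return the record with `depth_support` (and possibly flipped type,
#'   marked by `type_flipped = TRUE`).
#' @export
refine_with_depth <- function(record, dosage, ratio, tol = 0.25) {
  stopifnot(record$sv_type %in% c("DEL", "DUP"))
  if (is.na(ratio) || is.na(dosage) || dosage == 0L) return(record)
  exp_del <- 1 - 0.5 * dosage
  exp_dup <- 1 + 0.5 * dosage
  own <- if (record$sv_type == "DEL") exp_del else exp_dup
  other <- if (record$sv_type == "DEL") exp_dup else exp_del
  if (abs(ratio - own) <= tol) {
    record$depth_support <- TRUE
  } else if (abs(ratio - other) <= tol) {
    new_type <- if (record$sv_type == "DEL") "DUP" else "DEL"
    record$sv_type <- new_type
    record$svlen <- if (new_type == "DEL") -abs(record$svlen) else
      abs(record$svlen)
    record$depth_support <- TRUE
    record$type_flipped <- TRUE
  } else {
    record$depth_support <- FALSE
  }
  record
}
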