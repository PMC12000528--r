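## Alignment and reference I/O. Downstream modules consume the plain-list
## ReadAlignment records produced here, never raw files.

#' Construct a ReadAlignment record
#'
#' Internal container for one mapped read segment. Coordinates are 0-based
#' half-open; `seq` is stored in reference-strand orientation (as in BAM).
#'
#' @param read_id,sample_id identifiers; split segments of one read share
#'   `read_id`.
#' @param contig reference sequence name.
#' @param start 0-based reference position of the first aligned base.
#' @param cigar list(op, len) as returned by `parse_cigar`, or a CIGAR string.
#' @param seq read sequence (reference strand), possibly "".
#' @param mapq mapping quality 0-60.
#' @param is_reverse logical, original read strand.
#' @param supplementary_of `NA` for primary records, otherwise the read_id
#'   this supplementary segment belongs to.
#' @return object of class `ReadAlignment` (a list).
#' @export
read_alignment <- function(read_id, sample_id, contig, start, cigar, seq = "",
                           mapq = 60L, is_reverse = FALSE,
                           supplementary_of = NA_character_) {
  if (is.character(cigar)) cigar <- parse_cigar(cigar)
  if (nzchar(seq)) {
    stopifnot(cigar_query_len(cigar) == nchar(seq))
  }
  structure(list(read_id = read_id, sample_id = sample_id, contig = contig,
                 start = as.integer(start), cigar = cigar, seq = seq,
                 mapq = as.integer(mapq), is_reverse = isTRUE(is_reverse),
                 supplementary_of = supplementary_of),
            class = "ReadAlignment")
}

#' Load mapped long-read alignments from an indexed BAM
#'
#' Yields primary and supplementary records overlapping `region` with
#' mapping quality at least `min_mapq`; secondary records are excluded.
#' Split segments of one read share their `read_id`, with supplementary
#' segments linked through `supplementary_of`.
#'
#' @param path coordinate-sorted, indexed BAM file.
#' @param sample_id sample label attached to every record.
#' @param region optional `GRanges` of length 1 (or NULL for whole file).
#' @param min_mapq minimum mapping quality (default 10 for discovery; use 0
#'   when re-scoring reads at genotyping time).
#' @return list of `ReadAlignment` records.
#' @export
load_alignments <- function(path, sample_id, region = NULL, min_mapq = 10L) {
  if (!file.exists(path)) stop("BAM file not found: ", path)
  idx <- paste0(path, ".bai")
  if (!file.exists(idx) && !file.exists(sub("\\.bam$", ".bai", path))) {
    stop("BAM index (.bai) missing for ", path,
         "; sort and index the file (e.g. samtools sort + index) first")
  }
  flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                 isUnmappedQuery = FALSE)
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq")
  param <- if (is.null(region)) {
    Rsamtools::ScanBamParam(flag = flag, what = what)
  } else {
    Rsamtools::ScanBamParam(flag = flag, what = what, which = region)
  }
  chunks <- Rsamtools::scanBam(path, param = param)
  out <- list()
  for (ch in chunks) {
    n <- length(ch$qname)
    if (n == 0L) next
    keep <- ch$mapq >= min_mapq
    seqs <- as.character(ch$seq)
    for (i in which(keep)) {
      suppl <- bitwAnd(ch$flag[i], 2048L) > 0L
      out[[length(out) + 1L]] <- read_alignment(
        read_id = ch$qname[i], sample_id = sample_id,
        contig = as.character(ch$rname[i]), start = ch$pos[i] - 1L,
        cigar = ch$cigar[i], seq = seqs[i], mapq = ch$mapq[i],
        is_reverse = bitwAnd(ch$flag[i], 16L) > 0L,
        supplementary_of = if (suppl) ch$qname[i] else NA_character_)
    }
  }
  ## de-duplicate records fetched twice through overlapping region queries
  if (length(out) > 1L) {
    key <- vapply(out, function(a)
      paste(a$read_id, a$contig, a$start, cigar_string(a$cigar), sep = "\r"),
      character(1))
    out <- out[!duplicated(key)]
  }
  out
}

#' Fetch an uppercase reference window
#'
#' @param fasta path to an indexed FASTA (.fai created if absent).
#' @param contig sequence name.
#' @param start,end 0-based half-open interval; `end` beyond the contig is
#'   clamped with a warning.
#' @return list(contig, start, end, seq) — a `ReferenceWindow`.
#' @export
fetch_reference <- function(fasta, contig, start, end) {
  fa <- Rsamtools::FaFile(fasta)
  if (!file.exists(paste0(fasta, ".fai"))) Rsamtools::indexFa(fasta)
  info <- Rsamtools::seqinfo(fa)
  if (!contig %in% GenomeInfoDb::seqnames(info)) {
    stop("Unknown contig: ", contig)
  }
  clen <- GenomeInfoDb::seqlengths(info)[[contig]]
  stopifnot(start >= 0, start <= end)
  if (end > clen) {
    warning("Window end ", end, " beyond contig length ", clen, "; clamping")
    end <- clen
    if (start > end) start <- end
  }
  if (start == end) {
    return(structure(list(contig = contig, start = start, end = end, seq = ""),
                     class = "ReferenceWindow"))
  }
  gr <- GenomicRanges::GRanges(contig, IRanges::IRanges(start + 1L, end))
  seq <- toupper(as.character(Rsamtools::scanFa(fa, gr)[[1]]))
  structure(list(contig = contig, start = as.integer(start),
                 end = as.integer(end), seq = seq),
            class = "ReferenceWindow")
}

#' Contig lengths of an indexed FASTA
#' @param fasta path to FASTA.
#' @return named integer vector.
#' @export
reference_lengths <- function(fasta) {
  if (!file.exists(paste0(fasta, ".fai"))) Rsamtools::indexFa(fasta)
  info <- Rsamtools::seqinfo(Rsamtools::FaFile(fasta))
  stats::setNames(as.integer(GenomeInfoDb::seqlengths(info)),
                  GenomeInfoDb::seqnames(info))
}
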