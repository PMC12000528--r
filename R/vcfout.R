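## Multi-sample VCF 4.2 serialization: sequence-resolved small DEL/INS,
## symbolic large DEL and all DUP/INV (with END), component BND records in
## bracket notation for multi-breakpoint events, HOMLEN/HOMSEQ annotation
## and per-sample GT:GQ:AD:PS columns.

vcf_header <- function(contig_lengths, samples) {
  c("##fileformat=VCFv4.2",
    "##source=haplosv",
    sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
            as.integer(contig_lengths)),
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=DUP,Description=\"Tandem duplication\">",
    "##ALT=<ID=INV,Description=\"Inversion\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Signed SV length\">",
    "##INFO=<ID=HOMLEN,Number=1,Type=Integer,Description=\"Length of breakpoint microhomology\">",
    "##INFO=<ID=HOMSEQ,Number=1,Type=String,Description=\"Microhomology sequence at canonical placement\">",
    "##INFO=<ID=INSLEN,Number=1,Type=Integer,Description=\"Length of breakpoint insertion\">",
    "##INFO=<ID=EVENT,Number=1,Type=String,Description=\"Multi-breakpoint event id\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Id of mate breakend\">",
    "##INFO=<ID=DEPTHSUPPORT,Number=0,Type=Flag,Description=\"Depth signature supports the call\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Per-allele supporting read counts\">",
    "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

format_gt_field <- function(g, n_alleles, allele_map = NULL) {
  map1 <- function(a) {
    if (!is.null(allele_map)) {
      if (a == 0L) "0" else if (a %in% allele_map) "1" else "."
    } else as.character(a)
  }
  if (is.null(g) || is.null(g$gt)) {
    gt <- "./."
  } else if (isTRUE(g$phased) && !is.null(g$gt_ordered)) {
    gt <- paste(vapply(g$gt_ordered, map1, character(1)), collapse = "|")
  } else {
    gt <- paste(vapply(sort(g$gt), map1, character(1)), collapse = "/")
  }
  ad <- if (!is.null(g) && !is.null(g$ad)) {
    counts <- rep(0L, n_alleles + 1L)
    counts[seq_along(g$ad)] <- g$ad
    if (!is.null(allele_map)) counts <- counts[c(1L, allele_map + 1L)]
    paste(counts, collapse = ",")
  } else "."
  gq <- if (!is.null(g)) as.character(g$gq) else "0"
  ps <- if (!is.null(g) && isTRUE(g$phased) && !is.null(g$ps))
    as.character(g$ps + 1L) else "."
  paste(gt, gq, ad, ps, sep = ":")
}

info_string <- function(kv) {
  parts <- character(0)
  for (k in names(kv)) {
    v <- kv[[k]]
    if (is.null(v) || (length(v) == 1L && is.na(v))) next
    if (isTRUE(v)) parts <- c(parts, k)
    else parts <- c(parts, paste0(k, "=", v))
  }
  if (length(parts) == 0L) "." else paste(parts, collapse = ";")
}

bnd_alt <- function(ref_base, src_orient, mate) {
  mate_pos1 <- if (mate$orient == "left_anchor") mate$pos else mate$pos + 1L
  loc <- paste0(mate$contig, ":", mate_pos1)
  if (src_orient == "left_anchor") {
    if (mate$orient == "right_anchor") paste0(ref_base, "[", loc, "[")
    else paste0(ref_base, "]", loc, "]")
  } else {
    if (mate$orient == "left_anchor") paste0("]", loc, "]", ref_base)
    else paste0("[", loc, "[", ref_base)
  }
}

#' Write joint-genotyped SV loci to a multi-sample VCF
#'
#' DEL/INS shorter than `symbolic_threshold` are sequence-resolved
#' (left-anchor base included in REF and ALT); larger DEL and all DUP/INV
#' are symbolic with END. Inversions are reported both as a symbolic INV
#' and as their component BND records sharing an EVENT id. Phased
#' genotypes use '|' with a PS tag.
#'
#' @param loci list of genotyped `SvLocus` (each may carry a `components`
#'   list of BND records for multi-breakpoint events).
#' @param fasta reference FASTA path (REF bases are taken from it).
#' @param out output VCF path.
#' @param samples fixed sample column order.
#' @param symbolic_threshold size above which DEL becomes symbolic (10 kb).
#' @return invisibly, the output path.
#' @export
write_vcf <- function(loci, fasta, out, samples, symbolic_threshold = 10000L) {
  clen <- reference_lengths(fasta)
  refbase <- function(contig, pos0) {
    toupper(fetch_reference(fasta, contig, pos0, pos0 + 1L)$seq)
  }
  rows <- list()
  add_row <- function(contig, pos1, id, ref, alt, info, gts) {
    rows[[length(rows) + 1L]] <<- list(
      contig = contig, pos = pos1,
      line = paste(c(contig, pos1, id, ref, alt, ".", "PASS", info,
                     "GT:GQ:AD:PS", gts), collapse = "\t"))
  }
  for (l in loci) {
    k <- length(l$alleles)
    gts_for <- function(allele_map = NULL) {
      vapply(samples, function(s)
        format_gt_field(l$genotypes[[s]], k, allele_map), character(1))
    }
    multi_ok <- k > 1L &&
      all(vapply(l$alleles, function(a) length(a$records) == 1L, logical(1)))
    emit_record <- function(r, id, gts, extra_info = list()) {
      common <- list(SVTYPE = r$sv_type,
                     SVLEN = r$svlen,
                     HOMLEN = if (r$hom_len > 0L) r$hom_len else NULL,
                     HOMSEQ = if (r$hom_len > 0L) r$hom_seq else NULL,
                     EVENT = r$event_id,
                     DEPTHSUPPORT = if (isTRUE(r$depth_support)) TRUE else
                       NULL)
      if (r$sv_type == "DEL") {
        if (abs(r$svlen) < symbolic_threshold) {
          win <- fetch_reference(fasta, r$contig, r$pos - 1L, r$end)
          add_row(r$contig, r$pos, id, win$seq, substr(win$seq, 1L, 1L),
                  info_string(c(common, extra_info)), gts)
        } else {
          rb <- refbase(r$contig, r$pos - 1L)
          add_row(r$contig, r$pos, id, rb, "<DEL>",
                  info_string(c(common, list(END = r$end), extra_info)), gts)
        }
      } else if (r$sv_type == "INS") {
        rb <- refbase(r$contig, r$pos - 1L)
        add_row(r$contig, r$pos, id, rb, paste0(rb, r$ins_seq),
                info_string(c(common, list(INSLEN = r$svlen), extra_info)),
                gts)
      } else if (r$sv_type %in% c("DUP", "INV")) {
        rb <- refbase(r$contig, r$pos - 1L)
        add_row(r$contig, r$pos, id, rb, paste0("<", r$sv_type, ">"),
                info_string(c(common, list(END = r$end), extra_info)), gts)
      } else if (r$sv_type == "BND") {
        emit_bnd(r, id, gts)
      }
    }
    emit_bnd <- function(r, id, gts) {
      ids <- paste0(id, c("_1", "_2"))
      bes <- list(r$be1, r$be2)
      for (bi in 1:2) {
        be <- bes[[bi]]; mate <- bes[[3 - bi]]
        pos1 <- if (be$orient == "left_anchor") be$pos else be$pos + 1L
        rb <- refbase(be$contig, pos1 - 1L)
        info <- info_string(list(SVTYPE = "BND", MATEID = ids[3 - bi],
                                 EVENT = r$event_id))
        add_row(be$contig, pos1, ids[bi], rb, bnd_alt(rb, be$orient, mate),
                info, gts)
      }
    }
    if (multi_ok) {
      ## one multi-allelic row only when all alleles are sequence-resolved
      recs <- lapply(l$alleles, function(a) a$records[[1]])
      seq_ok <- all(vapply(recs, function(r)
        r$sv_type %in% c("DEL", "INS") && abs(r$svlen) < symbolic_threshold,
        logical(1))) &&
        length(unique(vapply(recs, function(r) r$pos, integer(1)))) == 1L &&
        all(vapply(recs, function(r) r$sv_type, character(1)) ==
              recs[[1]]$sv_type)
      if (seq_ok && recs[[1]]$sv_type == "INS") {
        rb <- refbase(l$contig, recs[[1]]$pos - 1L)
        alts <- vapply(recs, function(r) paste0(rb, r$ins_seq), character(1))
        add_row(l$contig, recs[[1]]$pos, l$locus_id, rb,
                paste(alts, collapse = ","),
                info_string(list(SVTYPE = "INS")), gts_for())
        next
      }
      if (seq_ok && recs[[1]]$sv_type == "DEL") {
        ends <- vapply(recs, function(r) r$end, integer(1))
        p0 <- recs[[1]]$pos - 1L
        win <- fetch_reference(fasta, l$contig, p0, max(ends))
        alts <- vapply(ends, function(e) paste0(
          substr(win$seq, 1L, 1L),
          substr(win$seq, e - p0 + 1L, nchar(win$seq))), character(1))
        add_row(l$contig, recs[[1]]$pos, l$locus_id, win$seq,
                paste(alts, collapse = ","),
                info_string(list(SVTYPE = "DEL")), gts_for())
        next
      }
      ## otherwise one row per allele, other alt alleles masked
      for (ai in seq_len(k)) {
        for (ri in seq_along(l$alleles[[ai]]$records)) {
          emit_record(l$alleles[[ai]]$records[[ri]],
                      paste0(l$locus_id, "_a", ai,
                             if (ri > 1L) paste0("_", ri) else ""),
                      gts_for(allele_map = ai))
        }
      }
    } else {
      for (ai in seq_len(k)) {
        amap <- if (k > 1L) ai else NULL
        for (ri in seq_along(l$alleles[[ai]]$records)) {
          emit_record(l$alleles[[ai]]$records[[ri]],
                      paste0(l$locus_id,
                             if (k > 1L) paste0("_a", ai) else "",
                             if (ri > 1L) paste0("_", ri) else ""),
                      gts_for(amap))
        }
      }
    }
    if (!is.null(l$components)) {
      for (ci in seq_along(l$components)) {
        emit_bnd(l$components[[ci]],
                 paste0(l$locus_id, "_bnd", ci), gts_for())
      }
    }
  }
  contig_order <- match(vapply(rows, function(r) r$contig, character(1)),
                        names(clen))
  pos <- vapply(rows, function(r) r$pos, numeric(1))
  body <- vapply(rows, function(r) r$line, character(1))[order(contig_order,
                                                               pos)]
  writeLines(c(vcf_header(clen, samples), body), out)
  invisible(out)
}

#' Read a (haplosv or generic SV) VCF for evaluation
#'
#' Lossy inverse of [write_vcf()]: reconstructs the fields needed for
#' truth comparison and pedigree concordance (type, position, end/len,
#' per-sample GT and GQ). Records without SVTYPE are skipped (count
#' reported via message).
#'
#' @param path VCF file.
#' @return data.frame with one row per record: contig, pos (1-based), id,
#'   svtype, end, svlen, plus GT_* and GQ_* columns per sample. The raw
#'   column strings are kept in attribute "body" for lossless re-rendering.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  header <- body[startsWith(body, "#CHROM")]
  stopifnot(length(header) == 1L)
  cols <- strsplit(sub("^#", "", header), "\t")[[1]]
  samples <- if (length(cols) > 9L) cols[10:length(cols)] else character(0)
  body <- body[!startsWith(body, "#")]
  if (length(body) == 0L) {
    df <- data.frame(contig = character(0), pos = integer(0),
                     id = character(0), svtype = character(0),
                     end = integer(0), svlen = integer(0))
    attr(df, "body") <- character(0)
    return(df)
  }
  mat <- do.call(rbind, strsplit(body, "\t"))
  info_get <- function(info, key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
    ifelse(lengths(regmatches(info, gregexpr(paste0("(^|;)", key, "="),
                                             info))) > 0,
           sub(paste0(".*", key, "="), "", m), NA_character_)
  }
  info <- mat[, 8]
  svtype <- vapply(info, function(x) {
    m <- regmatches(x, regexpr("(^|;)SVTYPE=[^;]*", x))
    if (length(m) == 0L) NA_character_ else sub(".*SVTYPE=", "", m)
  }, character(1), USE.NAMES = FALSE)
  keep <- !is.na(svtype)
  n_skip <- sum(!keep)
  if (n_skip > 0L) message("Skipped ", n_skip, " records without SVTYPE")
  mat <- mat[keep, , drop = FALSE]
  svtype <- svtype[keep]
  getk <- function(key) {
    vapply(mat[, 8], function(x) {
      m <- regmatches(x, regexpr(paste0("(^|;)", key, "=[^;]*"), x))
      if (length(m) == 0L) NA_integer_ else
        as.integer(sub(paste0(".*", key, "="), "", m))
    }, integer(1), USE.NAMES = FALSE)
  }
  df <- data.frame(contig = mat[, 1], pos = as.integer(mat[, 2]),
                   id = mat[, 3], svtype = svtype, end = getk("END"),
                   svlen = getk("SVLEN"), stringsAsFactors = FALSE)
  ## sequence-resolved records: derive end/svlen from REF/ALT
  symbolic <- grepl("[][<]", mat[, 5])
  seqres <- is.na(df$svlen) & !symbolic
  df$svlen[seqres] <- nchar(sub(",.*", "", mat[seqres, 5])) -
    nchar(mat[seqres, 4])
  del_sr <- df$svtype == "DEL" & is.na(df$end) & !symbolic
  df$end[del_sr] <- df$pos[del_sr] + nchar(mat[del_sr, 4]) - 1L
  if (length(samples)) {
    fmt <- strsplit(mat[, 9], ":")
    for (si in seq_along(samples)) {
      vals <- strsplit(mat[, 9L + si], ":")
      gt <- mapply(function(f, v) v[match("GT", f)], fmt, vals)
      gq <- suppressWarnings(as.integer(
        mapply(function(f, v) v[match("GQ", f)], fmt, vals)))
      df[[paste0("GT_", samples[si])]] <- unname(gt)
      df[[paste0("GQ_", samples[si])]] <- unname(gq)
    }
  }
  attr(df, "body") <- body[keep]
  attr(df, "samples") <- samples
  rownames(df) <- NULL
  df
}

#' Re-render the record body of a parsed VCF
#'
#' Column-lossless inverse of [read_vcf()] used to check write-read-write
#' stability.
#' @param df result of [read_vcf()].
#' @return character vector of record lines.
#' @export
render_vcf_body <- function(df) {
  attr(df, "body")
}
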