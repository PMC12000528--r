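## Two-phase driver mirroring the method's architecture: per-sample
## discovery (signatures -> clusters -> consensus haplotypes -> refined
## breakpoints + depth track), then multi-sample merging, genotyping,
## depth refinement, phasing and VCF output.

#' Default run configuration
#'
#' All module thresholds in one place; names match the corresponding
#' function arguments.
#' @param ... overrides of individual defaults.
#' @return list of class `RunConfig`.
#' @export
run_config <- function(...) {
  cfg <- list(
    min_mapq = 10L, min_signature_size = 35L, min_clip_size = 200L,
    max_gap = 50L, max_dist = 500L, size_ratio = 0.5,
    min_cluster_support = 2L, flank = 500L, max_haplotypes = 2L,
    split_threshold = 0.05, max_consensus_reads = 6L, min_size = 50L,
    min_identity = 0.9, max_span = 2e6, pair_tol = 1000L,
    bin_size = 1000L, min_depth_event_size = 5000L, depth_tol = 0.25,
    depth_flank = 5000L, epsilon = 0.05, min_score_margin = 10L,
    flank_score = 300L, max_direct = 2000L, max_merge_dist = 500L,
    merge_similarity = 0.99, symbolic_threshold = 10000L, version = "1")
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "RunConfig")
}

cluster_kind <- function(cl) {
  kp <- cl$kind_profile[setdiff(names(cl$kind_profile), "SOFTCLIP")]
  names(kp)[which.max(kp)]
}

#' Per-sample SV discovery
#'
#' Runs signature extraction, clustering, consensus assembly, reference
#' realignment with breakpoint refinement (including duplication testing
#' and inversion pairing) and depth-track construction for one sample.
#'
#' @param bam indexed BAM of mapped long reads.
#' @param fasta indexed reference FASTA.
#' @param sample_id sample label.
#' @param cfg a `RunConfig`.
#' @return discovery object: list(sample_id, haps, invs, bnds,
#'   inv_support, depth, config).
#' @export
run_discover <- function(bam, fasta, sample_id, cfg = run_config()) {
  if (!file.exists(bam)) stop("Missing BAM: ", bam)
  if (!file.exists(fasta)) stop("Missing FASTA: ", fasta)
  clens <- reference_lengths(fasta)
  haps <- list(); bnds <- list(); inv_support <- list()
  depth <- list()
  n_sig <- 0L; n_clust <- 0L
  for (contig in names(clens)) {
    region <- GenomicRanges::GRanges(contig,
                                     IRanges::IRanges(1L, clens[[contig]]))
    alns <- load_alignments(bam, sample_id, region, min_mapq = cfg$min_mapq)
    depth[[contig]] <- build_depth_track(alns, clens[[contig]],
                                         bin_size = cfg$bin_size)
    if (length(alns) == 0L) next
    sigs <- scan_signatures(alns, cfg$min_signature_size, cfg$min_clip_size,
                            cfg$max_gap)
    n_sig <- n_sig + nrow(sigs)
    clusters <- cluster_signatures(sigs, cfg$max_dist, cfg$size_ratio,
                                   cfg$min_cluster_support)
    n_clust <- n_clust + length(clusters)
    for (cl in clusters) {
      kind <- cluster_kind(cl)
      if (kind == "SPLIT_JUNCTION") {
        b <- bnd_from_junction_cluster(cl, hap_ref = paste0(sample_id, ":",
                                                            cl$cluster_id))
        if (!is.null(b)) {
          b$support_reads <- unique(cl$members$read_id)
          bnds[[length(bnds) + 1L]] <- b
        }
        next
      }
      hlist <- assemble_cluster(cl, alns, flank = cfg$flank,
                                contig_len = clens[[contig]],
                                max_haplotypes = cfg$max_haplotypes,
                                split_threshold = cfg$split_threshold,
                                min_support = cfg$min_cluster_support,
                                max_consensus_reads = cfg$max_consensus_reads)
      for (hap in hlist) {
        ref <- fetch_reference(fasta, contig, hap$anchor[["start"]],
                               hap$anchor[["end"]])
        aln <- align_haplotype(hap, ref)
        if (is.null(aln)) next
        recs <- extract_breakpoints(aln, hap, ref, min_size = cfg$min_size)
        recs <- lapply(recs, recanonicalize_record, fasta = fasta,
                       contig_len = clens[[contig]])
        recs <- lapply(recs, function(r) {
          if (r$sv_type != "INS") return(r)
          pad <- abs(r$svlen) + 50L
          dwin <- fetch_reference(fasta, contig, max(0L, r$pos - pad),
                                  min(clens[[contig]], r$pos + pad))
          classify_duplication(r, dwin, min_identity = cfg$min_identity)
        })
        if (length(recs)) {
          hap$records <- recs
          haps[[length(haps) + 1L]] <- hap
        }
      }
    }
  }
  paired <- pair_inversion(bnds, max_span = cfg$max_span,
                           pair_tol = cfg$pair_tol, min_size = cfg$min_size)
  invs <- Filter(function(r) r$sv_type == "INV", paired)
  out_bnds <- Filter(function(r) r$sv_type == "BND", paired)
  for (iv in invs) {
    comp <- Filter(function(b) identical(b$event_id, iv$event_id), out_bnds)
    inv_support[[iv$event_id]] <- unique(unlist(
      lapply(comp, function(b) b$support_reads)))
  }
  message(sprintf(
    "[%s] %d signatures, %d clusters, %d haplotypes, %d INV, %d BND",
    sample_id, n_sig, n_clust, length(haps), length(invs),
    length(out_bnds)))
  structure(list(sample_id = sample_id, haps = haps, invs = invs,
                 bnds = out_bnds, inv_support = inv_support, depth = depth,
                 config = cfg),
            class = "Discovery")
}

#' Write a discovery archive (plain-directory artifact)
#'
#' Human-inspectable archive: haplotype FASTA, candidate-record and depth
#' tables, config snapshot.
#' @param disc a discovery object.
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
write_discovery <- function(disc, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, "haplotypes.fasta")
  lines <- character(0)
  for (h in disc$haps) {
    lines <- c(lines, paste0(">", h$hap_id, " contig=", h$contig,
                             " anchor=", h$anchor[["start"]], "-",
                             h$anchor[["end"]],
                             " support=", paste(h$support_reads,
                                                collapse = ",")),
               h$seq)
  }
  writeLines(lines, fa)
  rec_df <- records_to_df(c(
    unlist(lapply(disc$haps, function(h) h$records), recursive = FALSE),
    disc$invs, disc$bnds))
  utils::write.table(rec_df, file.path(dir, "candidates.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  dep <- do.call(rbind, lapply(names(disc$depth), function(cn)
    data.frame(contig = cn, bin = seq_along(disc$depth[[cn]]$bins) - 1L,
               depth = disc$depth[[cn]]$bins)))
  utils::write.table(dep, file.path(dir, "depth.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  cfgl <- unclass(disc$config)
  jsonlite::write_json(c(list(sample_id = disc$sample_id),
                         cfgl), file.path(dir, "config.json"),
                       auto_unbox = TRUE)
  inv_sup <- lapply(disc$inv_support, identity)
  jsonlite::write_json(inv_sup, file.path(dir, "inv_support.json"))
  invisible(dir)
}

records_to_df <- function(recs) {
  cols <- c("sv_type", "contig", "pos", "end", "svlen", "ins_seq",
            "hom_len", "hom_seq", "event_id", "hap_ref",
            "be1_contig", "be1_pos", "be1_orient",
            "be2_contig", "be2_pos", "be2_orient")
  if (length(recs) == 0L) {
    df <- data.frame(matrix(nrow = 0L, ncol = length(cols)))
    colnames(df) <- cols
    return(df)
  }
  do.call(rbind, lapply(recs, function(r)
    data.frame(sv_type = r$sv_type, contig = r$contig, pos = r$pos,
               end = r$end, svlen = r$svlen, ins_seq = r$ins_seq,
               hom_len = r$hom_len, hom_seq = r$hom_seq,
               event_id = r$event_id, hap_ref = r$hap_ref,
               be1_contig = if (is.null(r$be1)) NA_character_ else r$be1$contig,
               be1_pos = if (is.null(r$be1)) NA_integer_ else r$be1$pos,
               be1_orient = if (is.null(r$be1)) NA_character_ else r$be1$orient,
               be2_contig = if (is.null(r$be2)) NA_character_ else r$be2$contig,
               be2_pos = if (is.null(r$be2)) NA_integer_ else r$be2$pos,
               be2_orient = if (is.null(r$be2)) NA_character_ else r$be2$orient,
               stringsAsFactors = FALSE)))
}

df_to_record <- function(row) {
  be1 <- if (!is.na(row$be1_contig))
    list(contig = row$be1_contig, pos = row$be1_pos,
         orient = row$be1_orient) else NULL
  be2 <- if (!is.na(row$be2_contig))
    list(contig = row$be2_contig, pos = row$be2_pos,
         orient = row$be2_orient) else NULL
  sv_record(row$sv_type, row$contig, row$pos, row$end, row$svlen,
            ins_seq = if (is.na(row$ins_seq)) "" else row$ins_seq,
            hom_len = row$hom_len,
            hom_seq = if (is.na(row$hom_seq)) "" else row$hom_seq,
            hap_ref = row$hap_ref, event_id = row$event_id,
            be1 = be1, be2 = be2)
}

#' Read a discovery archive written by [write_discovery()]
#'
#' @param dir archive directory.
#' @return a discovery object equivalent to the [run_discover()] result.
#' @export
read_discovery <- function(dir) {
  cfgj <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  sample_id <- cfgj$sample_id
  cfg <- do.call(run_config, cfgj[setdiff(names(cfgj), "sample_id")])
  fa <- readLines(file.path(dir, "haplotypes.fasta"))
  haps <- list()
  i <- 1L
  while (i <= length(fa)) {
    if (startsWith(fa[i], ">")) {
      hdr <- sub("^>", "", fa[i])
      fields <- strsplit(hdr, " ")[[1]]
      kv <- strsplit(fields[-1], "=")
      vals <- stats::setNames(vapply(kv, `[`, character(1), 2L),
                              vapply(kv, `[`, character(1), 1L))
      anchor <- as.integer(strsplit(vals[["anchor"]], "-")[[1]])
      hap_id <- fields[1]
      haps[[hap_id]] <- structure(list(
        hap_id = hap_id, seq = fa[i + 1L],
        support_reads = strsplit(vals[["support"]], ",")[[1]],
        cluster_ref = as.integer(strsplit(hap_id, ":")[[1]][2]),
        anchor = c(start = anchor[1], end = anchor[2]),
        contig = vals[["contig"]], sample_id = sample_id,
        records = list()), class = "ConsensusHaplotype")
      i <- i + 2L
    } else i <- i + 1L
  }
  cand <- utils::read.table(file.path(dir, "candidates.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE,
                            colClasses = c(ins_seq = "character",
                                           hom_seq = "character"))
  invs <- list(); bnds <- list()
  for (ri in seq_len(nrow(cand))) {
    r <- df_to_record(cand[ri, ])
    if (r$sv_type == "INV") invs[[length(invs) + 1L]] <- r
    else if (r$sv_type == "BND") bnds[[length(bnds) + 1L]] <- r
    else if (r$hap_ref %in% names(haps)) {
      haps[[r$hap_ref]]$records <- c(haps[[r$hap_ref]]$records, list(r))
    }
  }
  dep <- utils::read.table(file.path(dir, "depth.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  depth <- lapply(split(dep, dep$contig), function(d)
    structure(list(contig = d$contig[1], bin_size = cfg$bin_size,
                   bins = d$depth[order(d$bin)]), class = "DepthTrack"))
  inv_support <- jsonlite::read_json(file.path(dir, "inv_support.json"),
                                     simplifyVector = TRUE)
  structure(list(sample_id = sample_id, haps = unname(haps), invs = invs,
                 bnds = bnds,
                 inv_support = as.list(inv_support), depth = depth,
                 config = cfg),
            class = "Discovery")
}

#' Multi-sample joint genotyping
#'
#' Merges the discovered haplotypes of all samples into loci, re-scores
#' every sample's reads against the locus alleles, genotypes, applies
#' depth refinement to unbalanced candidates, phases overlapping
#' heterozygous calls and writes a multi-sample VCF.
#'
#' @param discs list of discovery objects (same config version).
#' @param bams named character vector sample -> BAM path.
#' @param fasta reference FASTA.
#' @param out_vcf output VCF path.
#' @param cfg a `RunConfig`.
#' @return invisibly, the genotyped loci list.
#' @export
run_joint_call <- function(discs, bams, fasta, out_vcf, cfg = run_config()) {
  vers <- unique(vapply(discs, function(d) d$config$version, character(1)))
  if (length(vers) != 1L) stop("Discovery archives from mismatched config versions")
  samples <- vapply(discs, function(d) d$sample_id, character(1))
  names(discs) <- samples
  haps <- unlist(lapply(discs, function(d) d$haps), recursive = FALSE)
  loci <- merge_haplotypes(haps, cfg$max_merge_dist, cfg$merge_similarity)
  inv_by_sample <- lapply(discs, function(d) d$invs)
  sup_by_sample <- lapply(discs, function(d) d$inv_support)
  inv_loci <- merge_inv_loci(inv_by_sample, sup_by_sample,
                             cfg$max_merge_dist)
  ## attach component breakends to inversion loci
  for (i in seq_along(inv_loci)) {
    ev <- inv_loci[[i]]$alleles[[1]]$records[[1]]$event_id
    for (d in discs) {
      comp <- Filter(function(b) identical(b$event_id, ev), d$bnds)
      if (length(comp)) { inv_loci[[i]]$components <- comp; break }
    }
  }
  loci <- order_loci(c(loci, inv_loci))
  params <- genotype_params(cfg$epsilon, cfg$min_score_margin,
                            cfg$flank_score, cfg$max_direct)
  w <- params$flank_score
  for (li in seq_along(loci)) {
    l <- loci[[li]]
    pad <- w + 10L
    ref <- fetch_reference(fasta, l$contig,
                           max(0L, l$span[["start"]] - pad),
                           l$span[["end"]] + pad)
    windows <- build_scoring_windows(l, ref, params)
    region <- GenomicRanges::GRanges(
      l$contig, IRanges::IRanges(max(1L, l$span[["start"]] - w),
                                 l$span[["end"]] + w))
    for (s in samples) {
      alns <- load_alignments(bams[[s]], s, region, min_mapq = 0L)
      by_read <- split(alns, vapply(alns, function(a) a$read_id,
                                    character(1)))
      assign <- vapply(by_read, function(ra)
        score_read_vs_alleles(ra, windows, params), integer(1))
      k <- length(l$alleles)
      ad <- vapply(0:k, function(a) sum(assign == a, na.rm = TRUE),
                   integer(1))
      g <- genotype_locus(ad, params)
      g$ad <- ad
      g$assignments <- assign
      l$genotypes[[s]] <- g
    }
    loci[[li]] <- l
  }
  ## depth refinement of unbalanced candidates
  for (li in seq_along(loci)) {
    l <- loci[[li]]
    r <- l$alleles[[1]]$records[[1]]
    if (!r$sv_type %in% c("DEL", "DUP")) next
    if ((l$span[["end"]] - l$span[["start"]]) < cfg$min_depth_event_size)
      next
    verdicts <- list()
    for (s in samples) {
      g <- l$genotypes[[s]]
      if (is.null(g$gt) || all(g$gt == 0L)) next
      dosage <- sum(g$gt != 0L)
      tr <- discs[[s]]$depth[[l$contig]]
      ratio <- depth_ratio(tr, c(l$span[["start"]], l$span[["end"]]),
                           flank = cfg$depth_flank)
      verdicts[[s]] <- refine_with_depth(r, dosage, ratio,
                                         tol = cfg$depth_tol)
    }
    if (length(verdicts)) {
      supp <- vapply(verdicts, function(v) isTRUE(v$depth_support),
                     logical(1))
      flip <- vapply(verdicts, function(v) isTRUE(v$type_flipped),
                     logical(1))
      if (all(flip)) {
        loci[[li]]$alleles[[1]]$records[[1]] <- verdicts[[1]]
      } else {
        loci[[li]]$alleles[[1]]$records[[1]]$depth_support <- any(supp)
      }
    }
  }
  for (s in samples) loci <- phase_overlapping(loci, s)
  write_vcf(loci, fasta, out_vcf, samples,
            symbolic_threshold = cfg$symbolic_threshold)
  n_type <- table(vapply(loci, function(l)
    l$alleles[[1]]$records[[1]]$sv_type, character(1)))
  message("Joint call: ", length(loci), " loci (",
          paste(names(n_type), n_type, sep = "=", collapse = ", "), ")")
  invisible(loci)
}
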