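## Deterministic synthetic-data generator: a random reference with planted
## tandem-repeat arrays, diploid genomes with planted DEL/INS/DUP/INV
## events of chosen genotypes, long reads (~10-30 kb) with ~1% random
## errors, and their alignments constructed analytically by lifting read
## coordinates through the known haplotype-to-reference map (so no external
## mapper is needed and split reads across inversion junctions carry exact
## SA-tagged junctions).

#' Default planted-SV plan
#'
#' Twenty events spanning the three SV size strata (50-499, 500-4999,
#' >= 5000 bp) across DEL/INS/DUP/INV.
#' @return data.frame(type, size).
#' @export
default_sv_plan <- function() {
  data.frame(
    type = c(rep("DEL", 7), rep("INS", 7), rep("DUP", 3), rep("INV", 3)),
    size = c(60L, 150L, 400L, 900L, 2500L, 6000L, 12000L,
             75L, 220L, 450L, 1200L, 3000L, 5500L, 8000L,
             120L, 800L, 5200L,
             300L, 2500L, 7000L),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' @param seed master seed; every random draw derives from it.
#' @param contig contig name.
#' @param contig_len reference length in bp (default 1 Mb).
#' @param sv_plan data.frame(type, size) of events to plant.
#' @param repeat_fraction fraction of DEL/INS events (size <= 1 kb) placed
#'   inside planted tandem-repeat arrays to exercise microhomology.
#' @param hom_prop proportion of planted events that are homozygous.
#' @param carrier_prob probability a (non-pedigree) sample carries an event.
#' @param read_len_mean,read_len_sd read length distribution (Normal,
#'   truncated to [1 kb, 2 x mean]).
#' @param depth fold coverage per sample.
#' @param error_rate per-base error rate (substitutions and 1-3 bp indels).
#' @param samples character vector of sample ids.
#' @param pedigree optional list(founders = c(father, mother), children =
#'   c(...)); all samples derive genotypes from four founder haplotypes.
#' @param margin event-free zone at contig ends (default 20 kb).
#' @param spacing minimum distance between planted events (default 2 kb).
#' @return list of class `SimConfig`.
#' @export
sim_config <- function(seed = 0L, contig = "sim1", contig_len = 1000000L,
                       sv_plan = default_sv_plan(), repeat_fraction = 0.2,
                       hom_prop = 0.3, carrier_prob = 1.0,
                       read_len_mean = 15000L, read_len_sd = 3000L,
                       depth = 30, error_rate = 0.01, samples = "S1",
                       pedigree = NULL, margin = 20000L, spacing = 2000L) {
  stopifnot(all(sv_plan$size >= 50L))
  structure(list(seed = as.integer(seed), contig = contig,
                 contig_len = as.integer(contig_len), sv_plan = sv_plan,
                 repeat_fraction = repeat_fraction, hom_prop = hom_prop,
                 carrier_prob = carrier_prob,
                 read_len_mean = read_len_mean, read_len_sd = read_len_sd,
                 depth = depth, error_rate = error_rate, samples = samples,
                 pedigree = pedigree, margin = margin, spacing = spacing),
            class = "SimConfig")
}

#' Build the synthetic reference with planted repeat arrays
#'
#' Draws i.i.d. uniform DNA, plans the (non-overlapping, spaced) event
#' sites of `cfg$sv_plan`, and plants a tandem-repeat array at
#' `repeat_fraction` of the eligible (small DEL/INS) sites so those events
#' fall in repeats with non-trivial microhomology. Deterministic for a
#' fixed config.
#'
#' @param cfg a `SimConfig`.
#' @return list(seq, sites) where sites is data.frame(type, size, pos,
#'   in_repeat, unit).
#' @export
make_reference <- function(cfg) {
  set.seed(cfg$seed)
  seq <- rand_dna(cfg$contig_len)
  plan <- cfg$sv_plan
  n <- nrow(plan)
  sites <- plan
  sites$pos <- NA_integer_
  sites$in_repeat <- FALSE
  sites$unit <- NA_character_
  if (n > 0L) {
    usable <- cfg$contig_len - 2L * cfg$margin
    ## shuffle plan order along the contig, then slot events
    ord <- sample.int(n)
    slot <- usable / n
    for (k in seq_len(n)) {
      i <- ord[k]
      foot <- if (plan$type[i] == "INS") 0L else plan$size[i]
      lo <- cfg$margin + round((k - 1) * slot) + cfg$spacing
      hi <- cfg$margin + round(k * slot) - cfg$spacing - foot
      if (hi <= lo) stop("Contig too short for the requested SV plan")
      sites$pos[i] <- as.integer(lo + floor(stats::runif(1) * (hi - lo)))
    }
    eligible <- which(plan$type %in% c("DEL", "INS") & plan$size <= 1000L)
    n_rep <- round(cfg$repeat_fraction * length(eligible))
    if (n_rep > 0L) {
      rep_sites <- sample(eligible, n_rep)
      for (i in rep_sites) {
        u <- sample(2:10, 1)
        size <- as.integer(ceiling(plan$size[i] / u) * u)
        sites$size[i] <- size
        unit <- rand_dna(u)
        arr_len <- if (plan$type[i] == "DEL") size + 4L * u else 4L * u
        arr <- paste(rep(unit, ceiling(arr_len / u)), collapse = "")
        arr <- substr(arr, 1L, arr_len)
        s0 <- sites$pos[i] - 2L * u
        substr(seq, s0 + 1L, s0 + arr_len) <- arr
        sites$in_repeat[i] <- TRUE
        sites$unit[i] <- unit
      }
    }
  }
  list(seq = seq, sites = sites)
}

#' Plant SV genotypes and build per-sample diploid haplotypes
#'
#' Assigns each event a genotype per sample (hom/het mix for independent
#' samples; founder-haplotype transmission for pedigrees) and constructs
#' the two haplotype sequences of every sample together with their
#' haplotype-to-reference block maps. Truth records carry the canonical
#' (leftmost) coordinates and expected microhomology computed with the
#' sliding-placement model.
#'
#' @param cfg a `SimConfig`.
#' @param ref result of [make_reference()].
#' @return list(truth = data.frame, haps = nested list
#'   sample -> list(h1, h2) with blocks and seq, ins_seqs = list).
#' @export
plant_svs <- function(cfg, ref) {
  force(ref)  # evaluate before reseeding: the argument may consume RNG
  set.seed(cfg$seed + 1L)
  sites <- ref$sites
  n <- nrow(sites)
  samples <- cfg$samples
  ## inserted sequences (INS) drawn once, shared across samples
  ins_seqs <- vector("list", n)
  for (i in seq_len(n)) {
    if (sites$type[i] == "INS") {
      ins_seqs[[i]] <- if (isTRUE(sites$in_repeat[i])) {
        u <- sites$unit[i]
        substr(paste(rep(u, ceiling(sites$size[i] / nchar(u))),
                     collapse = ""), 1L, sites$size[i])
      } else rand_dna(sites$size[i])
    }
  }
  ## carriage matrix: samples x events x 2 haplotypes
  carry <- array(FALSE, dim = c(length(samples), n, 2L),
                 dimnames = list(samples, NULL, NULL))
  if (is.null(cfg$pedigree)) {
    for (s in seq_along(samples)) for (i in seq_len(n)) {
      if (stats::runif(1) > cfg$carrier_prob) next
      if (stats::runif(1) < cfg$hom_prop) {
        carry[s, i, ] <- TRUE
      } else {
        carry[s, i, sample(1:2, 1)] <- TRUE
      }
    }
  } else {
    ped <- cfg$pedigree
    stopifnot(all(c(ped$founders, ped$children) %in% samples))
    ## four founder haplotypes; each carries an event w.p. 1/2
    fh <- matrix(stats::runif(4L * n) < 0.5, nrow = 4L)
    f1 <- match(ped$founders[1], samples); f2 <- match(ped$founders[2], samples)
    carry[f1, , 1L] <- fh[1L, ]; carry[f1, , 2L] <- fh[2L, ]
    carry[f2, , 1L] <- fh[3L, ]; carry[f2, , 2L] <- fh[4L, ]
    for (ch in ped$children) {
      ci <- match(ch, samples)
      t1 <- sample(1:2, 1)  # haplotype transmitted by founder 1
      t2 <- sample(1:2, 1)
      carry[ci, , 1L] <- fh[t1, ]
      carry[ci, , 2L] <- fh[2L + t2, ]
    }
  }
  ## truth records with canonical coordinates and expected homology
  truth <- sites
  truth$contig <- cfg$contig
  truth$end <- ifelse(truth$type == "INS", truth$pos,
                      truth$pos + truth$size)
  truth$svlen <- ifelse(truth$type == "DEL", -truth$size, truth$size)
  truth$hom_len <- 0L
  truth$canonical_pos <- truth$pos
  win_pad <- 1000L
  for (i in seq_len(n)) {
    ws <- max(0L, truth$pos[i] - win_pad)
    we <- min(cfg$contig_len, truth$end[i] + win_pad)
    wseq <- substr(ref$seq, ws + 1L, we)
    if (truth$type[i] == "DEL") {
      h <- compute_homology(wseq, truth$pos[i] - ws, truth$end[i] - ws)
      truth$hom_len[i] <- h$hom_len
      truth$canonical_pos[i] <- ws + h$canonical_start
    } else if (truth$type[i] == "INS") {
      h <- compute_ins_homology(wseq, truth$pos[i] - ws, ins_seqs[[i]])
      truth$hom_len[i] <- h$hom_len
      truth$canonical_pos[i] <- ws + h$canonical_start
    }
  }
  truth$canonical_end <- ifelse(truth$type == "DEL",
                                truth$canonical_pos + truth$size,
                                ifelse(truth$type == "INS",
                                       truth$canonical_pos, truth$end))
  for (s in seq_along(samples)) {
    dosage <- carry[s, , 1L] + carry[s, , 2L]
    truth[[paste0("gt_", samples[s])]] <- dosage
    truth[[paste0("haps_", samples[s])]] <-
      paste0(carry[s, , 1L] * 1L, carry[s, , 2L] * 1L)
  }
  haps <- list()
  for (s in seq_along(samples)) {
    haps[[samples[s]]] <- lapply(1:2, function(h) {
      build_haplotype(ref$seq, sites, ins_seqs, which(carry[s, , h]))
    })
  }
  list(truth = truth, haps = haps, ins_seqs = ins_seqs)
}

## Build one haplotype: blocks map hap intervals to reference intervals
## (type R forward, V inverted, I insertion-only) plus the full sequence.
build_haplotype <- function(refseq, sites, ins_seqs, sv_idx) {
  sv_idx <- sv_idx[order(sites$pos[sv_idx])]
  blocks <- list()
  pieces <- character(0)
  cur <- 0L; hp <- 0L
  add_block <- function(type, rs, re, seq) {
    len <- if (type == "I") nchar(seq) else re - rs
    if (len == 0L) return(invisible())
    blocks[[length(blocks) + 1L]] <<- list(type = type, rs = rs, re = re,
                                           hs = hp, he = hp + len)
    pieces[length(pieces) + 1L] <<- if (type == "R")
      substr(refseq, rs + 1L, re)
    else if (type == "V") revcomp(substr(refseq, rs + 1L, re))
    else seq
    hp <<- hp + len
  }
  for (i in sv_idx) {
    p <- sites$pos[i]
    add_block("R", cur, p, NULL)
    if (sites$type[i] == "DEL") {
      cur <- p + sites$size[i]
    } else if (sites$type[i] == "INS") {
      add_block("I", p, p, ins_seqs[[i]])
      cur <- p
    } else if (sites$type[i] == "DUP") {
      e <- p + sites$size[i]
      add_block("R", p, e, NULL)
      add_block("I", e, e, substr(refseq, p + 1L, e))
      cur <- e
    } else if (sites$type[i] == "INV") {
      e <- p + sites$size[i]
      add_block("V", p, e, NULL)
      cur <- e
    }
  }
  add_block("R", cur, nchar(refseq), NULL)
  list(blocks = blocks, seq = paste(pieces, collapse = ""))
}

## Alignment op table of a clean read [s, e) on a haplotype: data.frame
## (op, len, rstart, strand, chain); M ops carry reference starts, chains
## split at strand changes (each chain becomes one SAM record).
read_ops <- function(blocks, s, e) {
  ops <- list()
  last_strand <- NA_character_; last_ref_end <- NA_integer_; chain <- 0L
  push <- function(op, len, rstart = NA_integer_, strand = NA_character_) {
    ops[[length(ops) + 1L]] <<- list(op = op, len = as.integer(len),
                                     rstart = as.integer(rstart),
                                     strand = strand, chain = chain)
  }
  for (b in blocks) {
    if (b$he <= s || b$hs >= e) next
    a <- max(s, b$hs); z <- min(e, b$he)
    if (b$type == "I") {
      if (chain == 0L) chain <- 1L
      push("I", z - a)
      next
    }
    strand <- if (b$type == "R") "+" else "-"
    rstart <- if (b$type == "R") b$rs + (a - b$hs) else b$re - (z - b$hs)
    rend <- rstart + (z - a)
    if (is.na(last_strand) || strand != last_strand) {
      chain <- chain + 1L
    } else if (strand == "+" && !is.na(last_ref_end) &&
               rstart > last_ref_end) {
      push("D", rstart - last_ref_end, strand = strand)
    }
    push("M", z - a, rstart, strand)
    last_strand <- strand
    last_ref_end <- if (strand == "+") rend else NA_integer_
  }
  do.call(rbind, lapply(ops, function(o)
    data.frame(op = o$op, len = o$len, rstart = o$rstart, strand = o$strand,
               chain = o$chain, stringsAsFactors = FALSE)))
}

## Inject sequencing errors into a read and its op table. Substitutions
## only change the sequence; 1-3 bp insertion/deletion errors split M ops.
apply_read_errors <- function(seq, ops, error_rate) {
  len <- nchar(seq)
  n_err <- stats::rbinom(1L, len, error_rate)
  if (n_err == 0L) return(list(seq = seq, ops = ops))
  pos <- sort(sample.int(len, min(n_err, len)))
  kind <- sample(c("S", "I", "D"), length(pos), replace = TRUE,
                 prob = c(0.75, 0.125, 0.125))
  ## substitutions, vectorized
  subs <- pos[kind == "S"]
  if (length(subs)) {
    ch <- strsplit(seq, "")[[1]]
    repl <- vapply(ch[subs], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    ch[subs] <- repl
    seq <- paste(ch, collapse = "")
  }
  ## indel errors applied right-to-left so earlier positions stay valid
  idx <- which(kind != "S")
  for (t in rev(idx)) {
    p <- pos[t]  # 1-based read position
    l <- sample(1:3, 1L)
    qcons <- ops$op %in% c("M", "I")
    qend <- cumsum(ifelse(qcons, ops$len, 0L))
    qstart <- qend - ifelse(qcons, ops$len, 0L)
    oi <- which(qcons & qstart < p & p <= qend)[1]
    if (is.na(oi)) next
    off <- p - qstart[oi]  # 1-based offset within op
    if (kind[t] == "I") {
      ins <- rand_dna(l)
      seq <- paste0(substr(seq, 1L, p), ins, substr(seq, p + 1L, nchar(seq)))
      if (ops$op[oi] == "I") {
        ops$len[oi] <- ops$len[oi] + l
      } else {
        ops <- op_split(ops, oi, off, list(op = "I", len = l))
      }
    } else {
      l <- min(l, ops$len[oi] - off + 1L)
      if (l <= 0L) next
      seq <- paste0(substr(seq, 1L, p - 1L),
                    substr(seq, p + l, nchar(seq)))
      if (ops$op[oi] == "I") {
        ops$len[oi] <- ops$len[oi] - l
      } else {
        ops <- op_split(ops, oi, off - 1L, list(op = "D", len = l),
                        del_query = l)
      }
    }
  }
  ops <- ops[ops$len > 0L, , drop = FALSE]
  list(seq = seq, ops = ops)
}

## Split M op `oi` after `off` query bases and splice `mid` between the
## halves, with strand-aware reference bookkeeping. `del_query` marks a
## deletion error: the mid D op consumes reference taken from the M op.
op_split <- function(ops, oi, off, mid, del_query = 0L) {
  o <- ops[oi, ]
  strand <- o$strand
  len2 <- o$len - off - del_query
  if (len2 < 0L) { len2 <- 0L }
  first <- o; first$len <- off
  second <- o; second$len <- len2
  midrow <- data.frame(op = mid$op, len = mid$len,
                       rstart = NA_integer_, strand = strand,
                       chain = o$chain, stringsAsFactors = FALSE)
  if (!is.na(strand) && strand == "-") {
    first$rstart <- o$rstart + o$len - off
    second$rstart <- o$rstart
    if (mid$op == "D") midrow$rstart <- o$rstart + len2
  } else {
    first$rstart <- o$rstart
    second$rstart <- o$rstart + off + del_query
    if (mid$op == "D") midrow$rstart <- o$rstart + off
  }
  rbind(if (oi > 1L) ops[seq_len(oi - 1L), ] else NULL,
        first, midrow, second,
        if (oi < nrow(ops)) ops[(oi + 1L):nrow(ops), ] else NULL)
}

## Render the SAM records of one read from its op table.
read_to_sam <- function(read_id, contig, seq, ops, mapq = 60L) {
  qcons <- ops$op %in% c("M", "I")
  qend <- cumsum(ifelse(qcons, ops$len, 0L))
  qstart <- qend - ifelse(qcons, ops$len, 0L)
  rlen <- nchar(seq)
  chains <- unique(ops$chain[!is.na(ops$chain) & ops$op == "M"])
  recs <- list()
  for (ci in chains) {
    sel <- which(ops$chain == ci)
    ## trim leading/trailing D and edge I (edge I becomes part of the clip)
    while (length(sel) && ops$op[sel[1]] %in% c("D", "I")) sel <- sel[-1]
    while (length(sel) && ops$op[sel[length(sel)]] %in% c("D", "I"))
      sel <- sel[-length(sel)]
    if (!length(sel)) next
    sub <- ops[sel, , drop = FALSE]
    strand <- sub$strand[which(sub$op == "M")[1]]
    qcon_sub <- sub$op %in% c("M", "I")
    qs <- min(qstart[sel][qcon_sub])
    span_q <- sum(sub$len[qcon_sub])
    pos <- min(sub$rstart[sub$op == "M"])
    cig_ops <- sub$op; cig_len <- sub$len
    if (!is.na(strand) && strand == "-") {
      cig_ops <- rev(cig_ops); cig_len <- rev(cig_len)
      lead <- rlen - (qs + span_q); trail <- qs
      out_seq <- revcomp(seq)
    } else {
      lead <- qs; trail <- rlen - (qs + span_q)
      out_seq <- seq
    }
    cig <- cigar_canonical(list(
      op = c(if (lead > 0L) "S", cig_ops, if (trail > 0L) "S"),
      len = as.integer(c(if (lead > 0L) lead, cig_len,
                         if (trail > 0L) trail))))
    recs[[length(recs) + 1L]] <- list(pos = pos, strand = strand,
                                      cigar = cigar_string(cig),
                                      seq = out_seq, m_sum = sum(
                                        sub$len[sub$op == "M"]))
  }
  if (length(recs) == 0L) return(character(0))
  prim <- which.max(vapply(recs, function(r) r$m_sum, numeric(1)))
  sam <- character(0)
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    flag <- 0L
    if (!is.na(r$strand) && r$strand == "-") flag <- flag + 16L
    if (i != prim) flag <- flag + 2048L
    sa <- ""
    if (length(recs) > 1L) {
      others <- setdiff(seq_along(recs), i)
      sa <- paste0("\tSA:Z:", paste(vapply(others, function(j)
        paste(contig, recs[[j]]$pos + 1L,
              if (!is.na(recs[[j]]$strand) && recs[[j]]$strand == "-")
                "-" else "+",
              recs[[j]]$cigar, mapq, 0L, sep = ","), character(1)),
        collapse = ";"), ";")
    }
    sam[i] <- paste0(paste(read_id, flag, contig, r$pos + 1L, mapq,
                           r$cigar, "*", 0L, 0L, r$seq, "*", sep = "\t"), sa)
  }
  sam
}

#' Simulate reads for one sample and write a sorted, indexed BAM
#'
#' Reads are sampled uniformly from each haplotype to `depth`/2 coverage,
#' lengths Normal(mean, sd) truncated to [1 kb, 2 x mean]; errors are
#' injected at `error_rate`, and each read's alignment is constructed from
#' the haplotype-to-reference liftover (split records with SA tags across
#' inversion junctions).
#'
#' @param cfg a `SimConfig`.
#' @param sample_hap list(h1, h2) from [plant_svs()].
#' @param out_prefix path prefix for the BAM.
#' @param seed_offset per-sample offset added to `cfg$seed`.
#' @return path of the sorted, indexed BAM.
#' @export
simulate_reads <- function(cfg, sample_hap, out_prefix, seed_offset = 0L) {
  force(sample_hap)
  set.seed(cfg$seed + 10L + seed_offset)
  sam_path <- paste0(out_prefix, ".sam")
  con <- file(sam_path, "w")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", cfg$contig, cfg$contig_len)), con)
  rid <- 0L
  for (h in 1:2) {
    hap <- sample_hap[[h]]
    hlen <- nchar(hap$seq)
    target <- cfg$depth / 2 * cfg$contig_len
    total <- 0
    while (total < target) {
      l <- round(stats::rnorm(1, cfg$read_len_mean, cfg$read_len_sd))
      l <- max(1000L, min(as.integer(2L * cfg$read_len_mean), as.integer(l)))
      if (l >= hlen) l <- hlen - 1L
      s <- floor(stats::runif(1) * (hlen - l))
      e <- s + l
      rid <- rid + 1L
      seq <- substr(hap$seq, s + 1L, e)
      ops <- read_ops(hap$blocks, s, e)
      if (is.null(ops) || !nrow(ops)) { total <- total + l; next }
      er <- apply_read_errors(seq, ops, cfg$error_rate)
      sam <- read_to_sam(sprintf("read_h%d_%06d", h, rid), cfg$contig,
                         er$seq, er$ops)
      if (length(sam)) writeLines(sam, con)
      total <- total + l
    }
  }
  close(con)
  bam <- Rsamtools::asBam(sam_path, destination = out_prefix,
                          overwrite = TRUE, indexDestination = TRUE)
  unlink(sam_path)
  bam
}

#' Generate a complete synthetic dataset
#'
#' Reference FASTA, per-sample sorted/indexed BAMs and the truth table,
#' fully determined by the configuration.
#'
#' @param cfg a `SimConfig`.
#' @param dir output directory (created).
#' @return list(fasta, bams = named character vector, truth, sites, haps).
#' @export
simulate_dataset <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref <- make_reference(cfg)
  fasta <- file.path(dir, "ref.fa")
  writeLines(c(paste0(">", cfg$contig),
               substring(ref$seq, seq(1, nchar(ref$seq), 70),
                         pmin(nchar(ref$seq),
                              seq(1, nchar(ref$seq), 70) + 69L))), fasta)
  Rsamtools::indexFa(fasta)
  planted <- plant_svs(cfg, ref)
  bams <- character(0)
  for (si in seq_along(cfg$samples)) {
    s <- cfg$samples[si]
    bams[s] <- simulate_reads(cfg, planted$haps[[s]],
                              file.path(dir, s), seed_offset = si * 101L)
  }
  list(fasta = fasta, bams = bams, truth = planted$truth,
       sites = ref$sites, haps = planted$haps)
}
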