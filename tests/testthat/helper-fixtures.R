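# Shared fixtures: tiny FASTA/BAM builders and brute-force oracles used by
# several test files. All fixtures are generated in code at test time.

write_test_fasta <- function(seqs, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "ref.fa")
  lines <- character(0)
  for (nm in names(seqs)) lines <- c(lines, paste0(">", nm), seqs[[nm]])
  writeLines(lines, path)
  Rsamtools::indexFa(path)
  path
}

write_test_bam <- function(sam_records, contigs, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  sam <- file.path(dir, "t.sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", names(contigs),
                       as.integer(contigs)),
               sam_records), sam)
  Rsamtools::asBam(sam, destination = file.path(dir, "t"),
                   overwrite = TRUE, indexDestination = TRUE)
}

sam_line <- function(qname, flag, rname, pos1, mapq, cigar, seq, tags = "") {
  paste0(paste(qname, flag, rname, pos1, mapq, cigar, "*", 0, 0, seq, "*",
               sep = "\t"), tags)
}

# Brute-force sliding-placement homology oracle: enumerate every deletion
# placement producing the identical alternate sequence.
oracle_del_homology <- function(ref, del_start, del_end) {
  n <- nchar(ref); size <- del_end - del_start
  alt <- paste0(substr(ref, 1, del_start), substr(ref, del_end + 1, n))
  valid <- integer(0)
  for (p in 0:(n - size)) {
    cand <- paste0(substr(ref, 1, p), substr(ref, p + size + 1, n))
    if (cand == alt) valid <- c(valid, p)
  }
  ## equivalent placements form a contiguous run around del_start
  run <- valid[abs(valid - del_start) <= n]
  runs <- split(run, cumsum(c(TRUE, diff(run) != 1L)))
  blk <- runs[[which(vapply(runs, function(r) del_start %in% r, logical(1)))]]
  cs <- min(blk)
  hl <- length(blk) - 1L
  list(hom_len = hl,
       hom_seq = if (hl > 0) substr(ref, cs + 1, cs + hl) else "",
       canonical_start = cs)
}

oracle_ins_homology <- function(ref, pos, ins) {
  n <- nchar(ref); m <- nchar(ins)
  alt <- paste0(substr(ref, 1, pos), ins, substr(ref, pos + 1, n))
  valid <- integer(0)
  for (p in 0:n) {
    ok <- substr(alt, 1, p) == substr(ref, 1, p) &&
      substr(alt, p + m + 1, n + m) == substr(ref, p + 1, n)
    if (ok) valid <- c(valid, p)
  }
  runs <- split(valid, cumsum(c(TRUE, diff(valid) != 1L)))
  blk <- runs[[which(vapply(runs, function(r) pos %in% r, logical(1)))]]
  cs <- min(blk)
  hl <- length(blk) - 1L
  list(hom_len = hl,
       hom_seq = if (hl > 0) substr(ref, cs + 1, min(n, cs + hl)) else "",
       canonical_start = cs,
       canonical_ins = substr(alt, cs + 1, cs + m))
}

# Independent direct evaluation of the binomial-mixture genotype model.
oracle_genotype <- function(r, a, eps = 0.05) {
  lik <- c(`0/0` = (1 - eps)^r * eps^a,
           `0/1` = 0.5^(r + a),
           `1/1` = eps^r * (1 - eps)^a)
  post <- lik / sum(lik)
  best <- which.max(post)
  list(gt = names(post)[best], posterior = unname(post[best]),
       gq = floor(-10 * log10(1 - post[best])), posteriors = post)
}

# Random-sequence helper with planted tandem repeats for homology tests.
repeat_seeded_ref <- function(n = 60) {
  base <- strsplit(haplosv:::rand_dna(n), "")[[1]]
  if (runif(1) < 0.7) {
    u <- haplosv:::rand_dna(sample(2:6, 1))
    reps <- sample(3:8, 1)
    s0 <- sample(seq_len(max(1, n - nchar(u) * reps)), 1)
    arr <- substr(paste(rep(u, reps), collapse = ""), 1, nchar(u) * reps)
    base[s0:(s0 + nchar(arr) - 1)] <- strsplit(arr, "")[[1]]
  }
  paste(base[1:n], collapse = "")
}

# Brute-force clustering oracle: exhaustive pairwise link matrix, then
# transitive closure by repeated boolean multiplication (a different
# enumeration from the union-find implementation).
oracle_clusters <- function(sigs, max_dist, size_ratio) {
  n <- nrow(sigs)
  link <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { link[i, j] <- TRUE; next }
    if (sigs$kind[i] != sigs$kind[j] || sigs$kind[i] == "SOFTCLIP") next
    if (abs(sigs$pos[i] - sigs$pos[j]) > max_dist) next
    if (sigs$kind[i] %in% c("INDEL_DEL", "INDEL_INS")) {
      if (min(sigs$size[i], sigs$size[j]) /
          max(sigs$size[i], sigs$size[j]) < size_ratio) next
    } else {
      if (!(identical(sigs$orient[i], sigs$orient[j]) &&
            identical(sigs$mate_orient[i], sigs$mate_orient[j]) &&
            abs(sigs$mate_pos[i] - sigs$mate_pos[j]) <= max_dist)) next
    }
    link[i, j] <- TRUE
  }
  reach <- link
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    comp[which(reach[i, ])] <- cid
  }
  comp
}

partition_sets <- function(groups, ids) {
  if (length(ids) == 0L) return(list())
  sets <- lapply(split(ids, groups), sort)
  unname(sets[order(vapply(sets, `[`, character(1), 1))])
}

# Memoized full-scale discovery + joint call shared by acceptance checks.
acceptance_cache <- new.env(parent = emptyenv())
acceptance_run <- function() {
  if (!is.null(acceptance_cache$res)) return(acceptance_cache$res)
  dir <- file.path(tempdir(), "haplosv-acc")
  cfg <- sim_config(seed = 0L, samples = "S1")
  ds <- simulate_dataset(cfg, dir)
  disc <- suppressMessages(run_discover(ds$bams[["S1"]], ds$fasta, "S1"))
  vcf <- file.path(dir, "calls.vcf")
  loci <- suppressMessages(run_joint_call(list(disc), ds$bams, ds$fasta, vcf))
  res <- list(ds = ds, disc = disc, vcf = vcf, loci = loci,
              parsed = read_vcf(vcf))
  acceptance_cache$res <- res
  res
}
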