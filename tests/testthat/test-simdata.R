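# The synthetic-data generator: determinism, truth consistency, coverage
# targets and liftover-constructed alignments.

small_plan <- data.frame(type = c("DEL", "INS", "INV"),
                         size = c(300L, 150L, 800L))

test_that("the generator is deterministic for a fixed config", {
  cfg <- sim_config(seed = 50, contig_len = 60000L, depth = 5,
                    sv_plan = small_plan, margin = 6000L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  a <- simulate_dataset(cfg, d1)
  b <- simulate_dataset(cfg, d2)
  expect_identical(readLines(a$fasta), readLines(b$fasta))
  expect_identical(a$truth, b$truth)
  la <- load_alignments(a$bams[[1]], "S", min_mapq = 0)
  lb <- load_alignments(b$bams[[1]], "S", min_mapq = 0)
  key <- function(x) sort(vapply(x, function(r)
    paste(r$read_id, r$start, haplosv:::cigar_string(r$cigar),
          substr(r$seq, 1, 30)), character(1)))
  expect_identical(key(la), key(lb))
})

test_that("reference length and repeat planting follow the config", {
  cfg <- sim_config(seed = 51, contig_len = 50000L,
                    sv_plan = data.frame(type = "DEL", size = 60L),
                    repeat_fraction = 0, margin = 5000L)
  ref <- make_reference(cfg)
  expect_equal(nchar(ref$seq), 50000)
  expect_false(any(ref$sites$in_repeat))
  cfg2 <- sim_config(seed = 51, contig_len = 50000L,
                     sv_plan = data.frame(type = c("DEL", "INS"),
                                          size = c(60L, 80L)),
                     repeat_fraction = 1, margin = 5000L)
  ref2 <- make_reference(cfg2)
  expect_true(all(ref2$sites$in_repeat))
  ## repeat-planted events carry the expected nonzero homology in truth
  pl <- plant_svs(cfg2, ref2)
  expect_true(all(pl$truth$hom_len > 0))
})

test_that("applying truth records to the reference reproduces haplotypes", {
  cfg <- sim_config(seed = 52, contig_len = 60000L, depth = 4,
                    sv_plan = small_plan, margin = 6000L, hom_prop = 1)
  ref <- make_reference(cfg)
  pl <- plant_svs(cfg, ref)
  ## independent reconstruction: apply events right-to-left with substr
  tr <- pl$truth[order(-pl$truth$pos), ]
  s <- ref$seq
  for (i in seq_len(nrow(tr))) {
    p <- tr$pos[i]; e <- tr$end[i]
    s <- switch(tr$type[i],
      DEL = paste0(substr(s, 1, p), substr(s, e + 1, nchar(s))),
      INS = paste0(substr(s, 1, p), pl$ins_seqs[[as.integer(rownames(tr)[i])]],
                   substr(s, p + 1, nchar(s))),
      DUP = paste0(substr(s, 1, e), substr(s, p + 1, e),
                   substr(s, e + 1, nchar(s))),
      INV = paste0(substr(s, 1, p),
                   haplosv:::revcomp(substr(s, p + 1, e)),
                   substr(s, e + 1, nchar(s))))
  }
  expect_identical(pl$haps[[1]][[1]]$seq, s)  # hom: both haplotypes equal
  expect_identical(pl$haps[[1]][[2]]$seq, s)
})

test_that("total read bases approximate the target depth", {
  cfg <- sim_config(seed = 53, contig_len = 100000L, depth = 12,
                    sv_plan = small_plan, margin = 6000L)
  ds <- simulate_dataset(cfg, withr::local_tempdir())
  alns <- load_alignments(ds$bams[[1]], "S", min_mapq = 0)
  prim <- Filter(function(a) is.na(a$supplementary_of), alns)
  bases <- sum(vapply(prim, function(a) nchar(a$seq), numeric(1)))
  expect_lt(abs(bases - 12 * 100000) / (12 * 100000), 0.05)
})

test_that("error-free reads carry the exact planted deletion in CIGAR", {
  cfg <- sim_config(seed = 54, contig_len = 60000L, depth = 6,
                    sv_plan = data.frame(type = "DEL", size = 300L),
                    error_rate = 0, hom_prop = 1, margin = 6000L,
                    repeat_fraction = 0)
  ds <- simulate_dataset(cfg, withr::local_tempdir())
  alns <- load_alignments(ds$bams[[1]], "S", min_mapq = 0)
  tr <- ds$truth
  found <- FALSE
  for (a in alns) {
    r <- a$start
    for (i in seq_along(a$cigar$op)) {
      op <- a$cigar$op[i]; l <- a$cigar$len[i]
      if (op == "D" && l == 300L) {
        expect_equal(r, tr$pos[1])
        found <- TRUE
      }
      if (op %in% c("M", "D")) r <- r + l
    }
  }
  expect_true(found)
})

test_that("reads across an inversion split with junctions at truth", {
  cfg <- sim_config(seed = 55, contig_len = 60000L, depth = 6,
                    sv_plan = data.frame(type = "INV", size = 3000L),
                    error_rate = 0, hom_prop = 1, margin = 8000L)
  ds <- simulate_dataset(cfg, withr::local_tempdir())
  alns <- load_alignments(ds$bams[[1]], "S", min_mapq = 0)
  tr <- ds$truth
  suppl <- Filter(function(a) !is.na(a$supplementary_of), alns)
  expect_gt(length(suppl), 0)
  rev_recs <- Filter(function(a) a$is_reverse, alns)
  expect_gt(length(rev_recs), 0)
  sigs <- scan_signatures(alns)
  sj <- sigs[sigs$kind == "SPLIT_JUNCTION", ]
  expect_gt(nrow(sj), 0)
  ## junction coordinates are exactly the planted breakpoints
  ll <- sj[sj$orient == "left_anchor" & sj$mate_orient == "left_anchor", ]
  rr <- sj[sj$orient == "right_anchor" & sj$mate_orient == "right_anchor", ]
  expect_true(all(c(nrow(ll), nrow(rr)) > 0))
  expect_true(all(ll$pos == tr$pos[1] & ll$mate_pos == tr$end[1]))
  expect_true(all(rr$pos == tr$pos[1] & rr$mate_pos == tr$end[1]))
  ## a read fully inside the inversion maps reverse without splitting
  inside <- Filter(function(a)
    a$is_reverse && is.na(a$supplementary_of) &&
      a$start >= tr$pos[1] && haplosv:::aln_ref_end(a) <= tr$end[1], alns)
  for (a in inside) {
    expect_false(a$read_id %in% vapply(suppl, function(s) s$read_id,
                                       character(1)))
  }
})
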