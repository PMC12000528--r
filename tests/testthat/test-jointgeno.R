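# Haplotype merging, the genotype model, read scoring and phasing.

mk_merge_hap <- function(seq, sample, support, anchor = c(start = 900L, end = 2100L),
                         recs = NULL, id = paste0(sample, ":0:0")) {
  if (is.null(recs)) recs <- list(sv_record("INS", "c1", 1500L, 1500L,
                                            60L, ins_seq = strrep("A", 60)))
  structure(list(hap_id = id, seq = seq, support_reads = support,
                 cluster_ref = 0L, anchor = anchor, contig = "c1",
                 sample_id = sample, records = recs),
            class = "ConsensusHaplotype")
}

test_that("identical haplotypes from two samples merge to one allele", {
  set.seed(20)
  s <- haplosv:::rand_dna(1200)
  loci <- merge_haplotypes(list(
    mk_merge_hap(s, "S1", c("a", "b", "c")),
    mk_merge_hap(s, "S2", c("d", "e"))))
  expect_length(loci, 1)
  expect_length(loci[[1]]$alleles, 1)
  expect_setequal(names(loci[[1]]$alleles[[1]]$support), c("S1", "S2"))
})

test_that("a 30 bp expansion difference keeps alleles distinct", {
  set.seed(21)
  s <- haplosv:::rand_dna(1000)
  s2 <- paste0(substr(s, 1, 500), strrep("CAG", 10), substr(s, 501, 1000))
  loci <- merge_haplotypes(list(
    mk_merge_hap(s, "S1", c("a", "b", "c")),
    mk_merge_hap(s2, "S2", c("d", "e"))), merge_similarity = 0.99)
  expect_length(loci, 1)
  expect_length(loci[[1]]$alleles, 2)
  ## allele order: descending support, so S1's allele is index 1
  expect_identical(names(loci[[1]]$alleles[[1]]$support), "S1")
})

test_that("singleton loci survive merging and self-merge is idempotent", {
  set.seed(22)
  s <- haplosv:::rand_dna(1000)
  one <- merge_haplotypes(list(mk_merge_hap(s, "S1", c("a", "b"))))
  expect_length(one, 1)
  twice <- merge_haplotypes(list(mk_merge_hap(s, "S1", c("a", "b")),
                                 mk_merge_hap(s, "S1", c("a", "b"),
                                              id = "S1:0:1")))
  expect_length(twice, 1)
  expect_length(twice[[1]]$alleles, 1)
  expect_identical(twice[[1]]$alleles[[1]]$seq, one[[1]]$alleles[[1]]$seq)
})

test_that("genotype posteriors match the direct binomial-mixture oracle", {
  params <- genotype_params(epsilon = 0.05)
  g1 <- genotype_locus(c(10L, 0L), params)
  expect_equal(g1$gt, c(0, 0))
  expect_equal(g1$gq, 27)
  g2 <- genotype_locus(c(6L, 6L), params)
  expect_equal(g2$gt, c(0, 1))
  expect_equal(g2$gq, 40)
  g0 <- genotype_locus(c(0L, 0L), params)
  expect_null(g0$gt)
  expect_equal(g0$gq, 0)

  set.seed(23)
  for (trial in 1:50) {
    r <- sample(0:40, 1); a <- sample(0:40, 1)
    if (r + a == 0) next
    got <- genotype_locus(c(r, a), params)
    want <- oracle_genotype(r, a, 0.05)
    expect_equal(sum(got$posteriors), 1, tolerance = 1e-12)
    expect_equal(unname(got$posteriors),
                 unname(want$posteriors[c("0/0", "0/1", "1/1")]),
                 tolerance = 1e-9)
    expect_identical(paste(got$gt, collapse = "/"), want$gt)
  }
})

test_that("GQ is monotone nondecreasing in depth at fixed allele fraction", {
  params <- genotype_params()
  for (ratio in list(c(1, 0), c(1, 1))) {
    gqs <- vapply(2:60, function(n) {
      ad <- as.integer(round(n * ratio / sum(ratio)))
      genotype_locus(ad, params)$gq
    }, integer(1))
    expect_true(all(diff(gqs) >= 0))
  }
})

test_that("read scoring assigns by margin and respects spanning guards", {
  set.seed(24)
  ref_seq <- haplosv:::rand_dna(2000)
  win <- structure(list(contig = "c1", start = 0L, end = 2000L,
                        seq = ref_seq), class = "ReferenceWindow")
  rec <- sv_record("DEL", "c1", 900L, 1000L, -100L)
  locus <- structure(list(locus_id = "L0", contig = "c1",
                          span = c(start = 900L, end = 1000L),
                          alleles = list(list(seq = NULL,
                                              records = list(rec),
                                              support = list())),
                          genotypes = list()), class = "SvLocus")
  params <- genotype_params()
  wins <- build_scoring_windows(locus, win, params)
  ref_read <- read_alignment("q1", "S", "c1", 0L, "2000M", ref_seq)
  alt_seq <- paste0(substr(ref_seq, 1, 900), substr(ref_seq, 1001, 2000))
  alt_read <- read_alignment("q2", "S", "c1", 0L, "900M100D1000M", alt_seq)
  expect_equal(score_read_vs_alleles(list(ref_read), wins, params), 0L)
  expect_equal(score_read_vs_alleles(list(alt_read), wins, params), 1L)
  ## read covering only the left flank is unassigned
  part <- read_alignment("q3", "S", "c1", 0L, "700M", substr(ref_seq, 1, 700))
  expect_true(is.na(score_read_vs_alleles(list(part), wins, params)))
  ## margin guard: identical allele windows can never separate
  same <- locus
  same$alleles <- list(list(seq = NULL,
                            records = list(sv_record("DEL", "c1", 900L,
                                                     1000L, -100L)),
                            support = list()),
                       list(seq = NULL,
                            records = list(sv_record("DEL", "c1", 900L,
                                                     1000L, -100L)),
                            support = list()))
  wins2 <- build_scoring_windows(same, win, params)
  expect_true(is.na(score_read_vs_alleles(list(alt_read), wins2, params)))
})

mk_geno_locus <- function(pos, end, assignments, gt = c(0L, 1L)) {
  rec <- sv_record("DEL", "c1", pos, end, -(end - pos))
  structure(list(locus_id = paste0("L", pos), contig = "c1",
                 span = c(start = pos, end = end),
                 alleles = list(list(seq = NULL, records = list(rec),
                                     support = list(), hap_ids = character(0))),
                 genotypes = list(S1 = list(gt = gt, gq = 50L,
                                            ad = c(5L, 5L),
                                            assignments = assignments,
                                            phased = FALSE, ps = NULL))),
            class = "SvLocus")
}

test_that("shared reads phase overlapping heterozygous loci", {
  reads <- paste0("r", 1:10)
  cis_a <- stats::setNames(c(rep(1L, 5), rep(0L, 5)), reads)
  loci <- list(mk_geno_locus(1000L, 1100L, cis_a),
               mk_geno_locus(1500L, 1600L, cis_a))
  out <- phase_overlapping(loci, "S1")
  g1 <- out[[1]]$genotypes$S1; g2 <- out[[2]]$genotypes$S1
  expect_true(g1$phased && g2$phased)
  expect_equal(g1$ps, g2$ps)
  expect_identical(g1$gt_ordered, g2$gt_ordered)  # cis

  trans_b <- stats::setNames(c(rep(0L, 5), rep(1L, 5)), reads)
  loci2 <- list(mk_geno_locus(1000L, 1100L, cis_a),
                mk_geno_locus(1500L, 1600L, trans_b))
  out2 <- phase_overlapping(loci2, "S1")
  expect_identical(out2[[1]]$genotypes$S1$gt_ordered, c(1L, 0L))
  expect_identical(out2[[2]]$genotypes$S1$gt_ordered, c(0L, 1L))

  ## conflicting evidence leaves the pair unphased
  confl <- stats::setNames(c(1L, 0L, 1L, 0L, rep(NA_integer_, 6)), reads)
  confl2 <- stats::setNames(c(1L, 1L, 0L, 0L, rep(NA_integer_, 6)), reads)
  loci3 <- list(mk_geno_locus(1000L, 1100L, confl),
                mk_geno_locus(1500L, 1600L, confl2))
  expect_message(out3 <- phase_overlapping(loci3, "S1"), "Conflicting")
  expect_false(isTRUE(out3[[2]]$genotypes$S1$phased))

  ## isolated het stays unphased
  single <- phase_overlapping(list(mk_geno_locus(1000L, 1100L, cis_a)), "S1")
  expect_false(isTRUE(single[[1]]$genotypes$S1$phased))
})
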