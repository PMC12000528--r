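# Homology computation, haplotype realignment, breakpoint extraction,
# duplication classification and inversion pairing.

test_that("deletion homology matches the worked repeat example", {
  h <- compute_homology("ACGTTATATATAGGCC", 5, 9)
  expect_equal(h$hom_len, 4)
  expect_identical(h$hom_seq, "TATA")
  expect_equal(h$canonical_start, 4)
  ## flanks sharing zero bases
  h0 <- compute_homology("AAAACGTTTT", 4, 6)
  expect_equal(h0$hom_len, 0)
  expect_identical(h0$hom_seq, "")
})

test_that("homology equals the sliding-placement oracle", {
  set.seed(10)
  for (trial in 1:200) {
    ref <- repeat_seeded_ref(60)
    size <- sample(2:10, 1)
    s <- sample(5:(60 - size - 5), 1)
    got <- compute_homology(ref, s, s + size)
    want <- oracle_del_homology(ref, s, s + size)
    expect_identical(got, want)
  }
})

test_that("insertion homology equals the sliding-placement oracle", {
  set.seed(11)
  for (trial in 1:200) {
    ref <- repeat_seeded_ref(60)
    pos <- sample(5:55, 1)
    ins <- if (runif(1) < 0.5) {
      ## repeat-compatible insertion: copy of adjacent sequence
      substr(ref, pos + 1, pos + sample(2:8, 1))
    } else haplosv:::rand_dna(sample(2:8, 1))
    if (!nzchar(ins)) next
    got <- compute_ins_homology(ref, pos, ins)
    want <- oracle_ins_homology(ref, pos, ins)
    expect_equal(got$hom_len, want$hom_len)
    expect_equal(got$canonical_start, want$canonical_start)
    expect_identical(got$hom_seq, want$hom_seq)
    expect_identical(got$canonical_ins, want$canonical_ins)
  }
})

mk_hap <- function(seq, id = "S:0:0") {
  structure(list(hap_id = id, seq = seq, support_reads = c("r1", "r2"),
                 cluster_ref = 0L, anchor = c(start = 0L, end = 0L),
                 contig = "c1", sample_id = "S"),
            class = "ConsensusHaplotype")
}
mk_win <- function(seq, start = 0L, contig = "c1") {
  structure(list(contig = contig, start = as.integer(start),
                 end = as.integer(start) + nchar(seq), seq = seq),
            class = "ReferenceWindow")
}

test_that("haplotype realignment recovers single large gap runs", {
  set.seed(12)
  ref <- haplosv:::rand_dna(1200)
  identity <- align_haplotype(mk_hap(ref), mk_win(ref))
  expect_identical(identity$cigar$op, "M")
  expect_equal(identity$score, 1200)

  del_hap <- paste0(substr(ref, 1, 600), substr(ref, 661, 1200))
  a <- align_haplotype(mk_hap(del_hap), mk_win(ref))
  expect_true(any(a$cigar$op == "D" & a$cigar$len == 60))

  ins_hap <- paste0(substr(ref, 1, 600), haplosv:::rand_dna(60),
                    substr(ref, 601, 1200))
  b <- align_haplotype(mk_hap(ins_hap), mk_win(ref))
  expect_true(any(b$cigar$op == "I" & b$cigar$len == 60))

  ## unrelated flanks are flagged low-confidence and dropped
  junk <- paste0(haplosv:::rand_dna(300), substr(ref, 301, 1200))
  expect_message(res <- align_haplotype(mk_hap(junk), mk_win(ref)),
                 "low-confidence")
  expect_null(res)
})

test_that("breakpoint extraction applies offsets and the size filter", {
  set.seed(13)
  ref <- haplosv:::rand_dna(1000)
  win <- mk_win(ref, start = 5000L)
  hap <- mk_hap(paste0(substr(ref, 1, 100), substr(ref, 161, 1000)))
  aln <- list(cigar = list(op = c("M", "D", "M"), len = c(100L, 60L, 840L)))
  recs <- extract_breakpoints(aln, hap, win, min_size = 50)
  expect_length(recs, 1)
  expect_equal(recs[[1]]$sv_type, "DEL")
  expect_equal(recs[[1]]$pos, 5100)
  expect_equal(recs[[1]]$end, 5160)
  expect_equal(recs[[1]]$svlen, -60)

  ins <- haplosv:::rand_dna(60)
  hap2 <- mk_hap(paste0(substr(ref, 1, 100), ins, substr(ref, 101, 1000)))
  aln2 <- list(cigar = list(op = c("M", "I", "M"), len = c(100L, 60L, 900L)))
  recs2 <- extract_breakpoints(aln2, hap2, win, min_size = 50)
  expect_equal(recs2[[1]]$sv_type, "INS")
  expect_equal(recs2[[1]]$pos, 5100)
  expect_equal(recs2[[1]]$svlen, 60)
  expect_identical(recs2[[1]]$ins_seq, ins)

  ## two sub-threshold runs yield nothing
  aln3 <- list(cigar = list(op = c("M", "D", "M", "D", "M"),
                            len = c(100L, 40L, 10L, 40L, 810L)))
  expect_length(extract_breakpoints(aln3, hap, win, min_size = 50), 0)
})

test_that("equivalent placements canonicalize to identical records", {
  ## a deletion inside a repeat array: two different alignment placements
  ## of the same event must produce the same canonical record
  arr <- paste0("ACGTAC", strrep("TA", 40), "GGCCAA")
  win <- mk_win(paste0(strrep("G", 100), arr, strrep("C", 100)), start = 0L)
  hap_seq <- paste0(substr(win$seq, 1, 110),
                    substr(win$seq, 121, nchar(win$seq)))
  a1 <- list(cigar = list(op = c("M", "D", "M"),
                          len = c(110L, 10L, nchar(win$seq) - 120L)))
  a2 <- list(cigar = list(op = c("M", "D", "M"),
                          len = c(120L, 10L, nchar(win$seq) - 130L)))
  r1 <- extract_breakpoints(a1, mk_hap(hap_seq), win, min_size = 10)
  r2 <- extract_breakpoints(a2, mk_hap(hap_seq), win, min_size = 10)
  expect_equal(r1[[1]]$pos, r2[[1]]$pos)
  expect_equal(r1[[1]]$hom_len, r2[[1]]$hom_len)
  expect_identical(r1[[1]]$hom_seq, r2[[1]]$hom_seq)
})

test_that("tandem copies reclassify as DUP, dispersed insertions stay INS", {
  set.seed(14)
  left <- haplosv:::rand_dna(400)
  copy <- haplosv:::rand_dna(100)
  right <- haplosv:::rand_dna(400)
  ref <- paste0(left, copy, right)
  win <- mk_win(ref, start = 0L)
  ## insertion of an exact copy right after the template
  rec <- sv_record("INS", "c1", 500L, 500L, 100L, ins_seq = copy)
  dup <- classify_duplication(rec, win)
  expect_equal(dup$sv_type, "DUP")
  expect_equal(dup$pos, 400)
  expect_equal(dup$end, 500)

  rnd <- sv_record("INS", "c1", 500L, 500L, 100L,
                   ins_seq = haplosv:::rand_dna(100))
  expect_equal(classify_duplication(rnd, win)$sv_type, "INS")

  ## 5% substitutions still pass at min_identity 0.9
  mut <- strsplit(copy, "")[[1]]
  idx <- sample(100, 5)
  mut[idx] <- vapply(mut[idx], function(b)
    setdiff(c("A", "C", "G", "T"), b)[1], character(1))
  noisy <- sv_record("INS", "c1", 500L, 500L, 100L,
                     ins_seq = paste(mut, collapse = ""))
  expect_equal(classify_duplication(noisy, win, min_identity = 0.9)$sv_type,
               "DUP")
})

mk_bnd <- function(p1, o1, p2, o2) {
  sv_record("BND", "c1", min(p1, p2),
            be1 = list(contig = "c1", pos = p1, orient = o1),
            be2 = list(contig = "c1", pos = p2, orient = o2))
}

test_that("inverted breakend pairs become INV events", {
  bnds <- list(mk_bnd(10000, "left_anchor", 15000, "left_anchor"),
               mk_bnd(10000, "right_anchor", 15000, "right_anchor"))
  out <- pair_inversion(bnds)
  invs <- Filter(function(r) r$sv_type == "INV", out)
  expect_length(invs, 1)
  expect_equal(invs[[1]]$pos, 10000)
  expect_equal(invs[[1]]$end, 15000)
  evs <- vapply(Filter(function(r) r$sv_type == "BND", out),
                function(r) r$event_id, character(1))
  expect_identical(unique(evs), invs[[1]]$event_id)

  ## deletion-orientation junctions never pair
  del_bnds <- list(mk_bnd(10000, "left_anchor", 15000, "right_anchor"),
                   mk_bnd(10010, "left_anchor", 15010, "right_anchor"))
  expect_length(Filter(function(r) r$sv_type == "INV",
                       pair_inversion(del_bnds)), 0)

  ## distant junctions respect max_span
  far <- list(mk_bnd(1e6, "left_anchor", 11e6, "left_anchor"),
              mk_bnd(1e6, "right_anchor", 11e6, "right_anchor"))
  out_far <- pair_inversion(far, max_span = 1e6)
  expect_length(Filter(function(r) r$sv_type == "INV", out_far), 0)
  expect_length(Filter(function(r) r$sv_type == "BND", out_far), 2)
})
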