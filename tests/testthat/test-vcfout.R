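# VCF serialization: coordinate conversion, homology annotation, breakend
# notation, phasing fields, round trips and external-parser validity.

build_vcf_fixture <- function(dir) {
  set.seed(40)
  refseq <- haplosv:::rand_dna(20000)
  ## deletion at [5100, 5160) (0-based) with exactly 4 bp of microhomology:
  ## both junction flanks start with TATA, bounded by mismatching bases
  ch <- strsplit(refseq, "")[[1]]
  ch[5100] <- "G"; ch[5160] <- "C"                 # 0-based 5099 / 5159
  ch[5101:5104] <- c("T", "A", "T", "A")           # 0-based 5100..5103
  ch[5161:5164] <- c("T", "A", "T", "A")           # 0-based 5160..5163
  ch[5105] <- "C"; ch[5165] <- "G"
  refseq <- paste(ch, collapse = "")
  fa <- write_test_fasta(list(c1 = refseq), dir)
  mk_locus <- function(id, rec, gt, gq, ad, phased = FALSE, ps = NULL,
                       gt_ordered = NULL, components = NULL) {
    structure(list(locus_id = id, contig = "c1",
                   span = c(start = rec$pos,
                            end = max(rec$pos, rec$end, na.rm = TRUE)),
                   alleles = list(list(seq = NULL, records = list(rec),
                                       support = list())),
                   genotypes = list(S1 = list(gt = gt, gq = gq, ad = ad,
                                              phased = phased, ps = ps,
                                              gt_ordered = gt_ordered)),
                   components = components), class = "SvLocus")
  }
  hom <- compute_homology(refseq, 5100, 5160)
  stopifnot(hom$hom_len == 4L, hom$canonical_start == 5100L)
  del <- sv_record("DEL", "c1", 5100L, 5160L, -60L,
                   hom_len = hom$hom_len, hom_seq = hom$hom_seq)
  ins <- sv_record("INS", "c1", 9000L, 9000L, 70L,
                   ins_seq = haplosv:::rand_dna(70))
  big_del <- sv_record("DEL", "c1", 11000L, 23000L, -12000L)
  inv <- sv_record("INV", "c1", 14000L, 15000L, 1000L, event_id = "EV1")
  b1 <- sv_record("BND", "c1", 14000L, event_id = "EV1",
                  be1 = list(contig = "c1", pos = 14000L, orient = "left_anchor"),
                  be2 = list(contig = "c1", pos = 15000L, orient = "left_anchor"))
  b2 <- sv_record("BND", "c1", 14000L, event_id = "EV1",
                  be1 = list(contig = "c1", pos = 14000L, orient = "right_anchor"),
                  be2 = list(contig = "c1", pos = 15000L, orient = "right_anchor"))
  loci <- list(
    mk_locus("L0", del, c(0L, 1L), 60L, c(8L, 7L), phased = TRUE,
             ps = 5100L, gt_ordered = c(1L, 0L)),
    mk_locus("L1", ins, c(1L, 1L), 80L, c(0L, 14L)),
    mk_locus("L2", big_del, c(0L, 1L), 55L, c(6L, 6L)),
    mk_locus("L3", inv, c(0L, 1L), 44L, c(5L, 6L),
             components = list(b1, b2)))
  out <- file.path(dir, "x.vcf")
  write_vcf(loci, fa, out, samples = "S1", symbolic_threshold = 10000L)
  list(fa = fa, vcf = out, loci = loci, refseq = refseq)
}

test_that("records round-trip through write and read", {
  fx <- build_vcf_fixture(withr::local_tempdir())
  df <- read_vcf(fx$vcf)
  del <- df[df$id == "L0", ]
  expect_equal(del$pos, 5100)       # left-anchored 1-based position
  expect_equal(del$svlen, -60)
  expect_equal(del$end, 5160)
  expect_match(attr(df, "body")[df$id == "L0"], "HOMLEN=4")
  expect_match(attr(df, "body")[df$id == "L0"], "HOMSEQ=TATA")
  expect_identical(del$GT_S1, "1|0")
  ins <- df[df$id == "L1", ]
  expect_equal(ins$svlen, 70)
  expect_identical(ins$GT_S1, "1/1")
  expect_identical(df$GT_S1[df$id == "L2"], "0/1")
  expect_equal(df$svtype[df$id == "L2"], "DEL")
  expect_match(attr(df, "body")[df$id == "L2"], "<DEL>")
  expect_equal(df$end[df$id == "L2"], 23000)
})

test_that("REF bases match the reference at POS for every record", {
  fx <- build_vcf_fixture(withr::local_tempdir())
  df <- read_vcf(fx$vcf)
  body <- attr(df, "body")
  for (line in body) {
    f <- strsplit(line, "\t")[[1]]
    pos <- as.integer(f[2]); ref <- f[4]
    expect_identical(ref, substr(fx$refseq, pos, pos + nchar(ref) - 1L))
  }
})

test_that("inversions emit an INV plus reciprocal BND mates under one event", {
  fx <- build_vcf_fixture(withr::local_tempdir())
  df <- read_vcf(fx$vcf)
  body <- attr(df, "body")
  ev_rows <- grep("EVENT=EV1", body, value = TRUE)
  expect_length(ev_rows, 5)  # 1 INV + 2 junctions x 2 breakends
  bnd <- df[df$svtype == "BND", ]
  expect_equal(nrow(bnd), 4)
  ## mate reciprocity: the MATEID row's ALT points back at this row's POS
  for (i in seq_len(nrow(bnd))) {
    line <- body[df$id == bnd$id[i]]
    mate_id <- sub(".*MATEID=([^;\t]+).*", "\\1", line)
    mate_line <- body[df$id == mate_id]
    expect_length(mate_line, 1)
    mate_alt <- strsplit(mate_line, "\t")[[1]][5]
    expect_match(mate_alt, paste0("c1:", bnd$pos[i], "[][]"))
    back_id <- sub(".*MATEID=([^;\t]+).*", "\\1", mate_line)
    expect_identical(back_id, bnd$id[i])
  }
})

test_that("writing is deterministic and write-read-render is byte-stable", {
  dir <- withr::local_tempdir()
  fx <- build_vcf_fixture(dir)
  out2 <- file.path(dir, "y.vcf")
  write_vcf(fx$loci, fx$fa, out2, samples = "S1",
            symbolic_threshold = 10000L)
  expect_identical(readLines(fx$vcf), readLines(out2))
  df <- read_vcf(fx$vcf)
  body <- grep("^#", readLines(fx$vcf), invert = TRUE, value = TRUE)
  expect_identical(render_vcf_body(df), body)
})

test_that("output parses with an independent VCF reader", {
  skip_if_not_installed("VariantAnnotation")
  fx <- build_vcf_fixture(withr::local_tempdir())
  v <- VariantAnnotation::readVcf(fx$vcf, genome = "sim")
  expect_equal(length(v), length(read_vcf(fx$vcf)$pos))
  gt <- VariantAnnotation::geno(v)$GT
  expect_identical(unname(gt[1, 1]), "1|0")
})

test_that("non-SV rows are skipped with a count", {
  dir <- withr::local_tempdir()
  fx <- build_vcf_fixture(dir)
  lines <- readLines(fx$vcf)
  extra <- "c1\t100\tsnp1\tA\tC\t.\tPASS\t.\tGT:GQ:AD:PS\t0/1:30:.:."
  writeLines(c(lines, extra), file.path(dir, "z.vcf"))
  expect_message(df <- read_vcf(file.path(dir, "z.vcf")), "Skipped 1")
  expect_false("snp1" %in% df$id)
  ## empty body parses to an empty table
  writeLines(grep("^#", lines, value = TRUE), file.path(dir, "e.vcf"))
  expect_equal(nrow(read_vcf(file.path(dir, "e.vcf"))), 0)
})
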