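# Pedigree concordance: Mendelian satisfiability search, MODE B maps,
# GQ filtering and behaviour under genotype errors.

ped7 <- pedigree(c("P1", "P2"), paste0("C", 1:5))

gt_list <- function(...) {
  v <- list(...)
  stats::setNames(v, ped7$samples[seq_along(v)])
}

test_that("worked family examples", {
  ## an allele absent from both parents is discordant
  g <- gt_list(c(0, 0), c(0, 0), c(0, 1), c(0, 0), c(0, 0), c(0, 0), c(0, 0))
  expect_identical(check_locus(g, ped7), "discordant")
  ## het x homref with het/homref children is concordant
  g2 <- gt_list(c(0, 1), c(0, 0), c(0, 1), c(0, 0), c(0, 1), c(0, 0), c(0, 1))
  expect_identical(check_locus(g2, ped7), "concordant")
  ## missing genotype anywhere -> unevaluated
  g3 <- g2; g3$C5 <- NULL
  expect_identical(check_locus(g3, ped7), "unevaluated")
})

test_that("MODE B fixes transmissions", {
  ped1 <- pedigree(c("P1", "P2"), "C1")
  g <- list(P1 = c(0, 1), P2 = c(0, 1), C1 = c(1, 1))
  inh <- list(C1 = c(1, 1))
  ## both parents transmit haplotype 1; a phasing with alt on both
  ## haplotype-1 copies exists, so the 1/1 child is concordant
  expect_identical(check_locus(g, ped1, inheritance = inh), "concordant")
  ## but a 0/0 child under the same map needs ref on both hap 1 copies,
  ## also satisfiable; a het child is satisfiable too -- make it fail:
  g2 <- list(P1 = c(1, 1), P2 = c(1, 1), C1 = c(0, 0))
  expect_identical(check_locus(g2, ped1, inheritance = inh), "discordant")
})

test_that("MODE A equals a brute-force per-child enumeration", {
  ## independent oracle: each child independently needs one allele from
  ## each parent's genotype
  oracle <- function(g, ped) {
    if (any(vapply(g[ped$samples], is.null, logical(1)))) return("unevaluated")
    fa <- g[[ped$founders[1]]]; mo <- g[[ped$founders[2]]]
    for (ch in ped$children) {
      cg <- sort(g[[ch]])
      ok <- FALSE
      for (x in fa) for (y in mo) if (identical(sort(c(x, y)), cg)) ok <- TRUE
      if (!ok) return("discordant")
    }
    "concordant"
  }
  set.seed(60)
  for (trial in 1:200) {
    nch <- sample(1:5, 1)
    ped <- pedigree(c("F", "M"), paste0("K", seq_len(nch)))
    g <- lapply(ped$samples, function(s) sort(sample(0:2, 2, replace = TRUE)))
    names(g) <- ped$samples
    expect_identical(check_locus(g, ped), oracle(g, ped))
  }
})

sim_ped_genotypes <- function(seed, err = 0) {
  cfg <- sim_config(seed = seed, contig_len = 60000L,
                    sv_plan = data.frame(type = rep(c("DEL", "INS"), 10),
                                         size = rep(c(80L, 120L), 10)),
                    margin = 5000L, spacing = 500L,
                    samples = c("P1", "P2", paste0("C", 1:5)),
                    pedigree = list(founders = c("P1", "P2"),
                                    children = paste0("C", 1:5)))
  ref <- make_reference(cfg)
  pl <- plant_svs(cfg, ref)
  gts <- lapply(seq_len(nrow(pl$truth)), function(i) {
    g <- lapply(cfg$samples, function(s) {
      d <- pl$truth[[paste0("gt_", s)]][i]
      if (runif(1) < err) d <- sample(setdiff(0:2, d), 1)
      switch(d + 1L, c(0L, 0L), c(0L, 1L), c(1L, 1L))
    })
    stats::setNames(g, cfg$samples)
  })
  list(gts = gts, ped = pedigree(c("P1", "P2"), paste0("C", 1:5)))
}

test_that("error-free pedigree genotypes are 100% concordant and errors
           reduce concordance monotonically", {
  set.seed(61)
  props <- vapply(c(0, 0.02, 0.05, 0.1), function(e) {
    sp <- sim_ped_genotypes(seed = 77, err = e)
    verdicts <- vapply(sp$gts, check_locus, character(1), ped = sp$ped)
    summarize_concordance(verdicts)$proportion
  }, numeric(1))
  expect_equal(props[1], 1.0)
  expect_true(all(diff(props) <= 0))
})

test_that("GQ filtering removes loci from both counts", {
  verdicts <- c(rep("concordant", 8), rep("discordant", 2))
  res <- summarize_concordance(verdicts)
  expect_equal(res$proportion, 0.8)
  gq <- matrix(99, 10, 7)
  gq[1, 3] <- 10  # one concordant locus fails the filter
  res40 <- summarize_concordance(verdicts, gq, min_gq = 40)
  expect_equal(res40$concordant, 7)
  expect_equal(res40$evaluated, 9)
  ## filter above every GQ: nothing evaluated, proportion missing
  res_hi <- summarize_concordance(verdicts, gq, min_gq = 1000)
  expect_equal(res_hi$evaluated, 0)
  expect_true(is.na(res_hi$proportion))
  ## evaluated count is nonincreasing in min_gq
  gq2 <- matrix(sample(0:99, 70, replace = TRUE), 10, 7)
  evals <- vapply(seq(0, 100, by = 10), function(q)
    summarize_concordance(verdicts, gq2, min_gq = q)$evaluated, integer(1))
  expect_true(all(diff(evals) <= 0))
})

test_that("PED files parse to the founder-couple pedigree", {
  dir <- withr::local_tempdir()
  ped_path <- file.path(dir, "fam.ped")
  writeLines(c("FAM1 P1 0 0 1 1", "FAM1 P2 0 0 2 1",
               paste("FAM1", paste0("C", 1:5), "P1 P2 1 1")), ped_path)
  ped <- read_pedigree(ped_path)
  expect_identical(ped$founders, c("P1", "P2"))
  expect_length(ped$children, 5)
})
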