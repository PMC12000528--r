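## Pedigree genotype-concordance evaluation: per locus, decide whether the
## genotypes called across all family members can be produced by Mendelian
## transmission (MODE A) or by a fixed, known inheritance pattern (MODE B),
## then summarize counts and proportions under GQ filters.

#' Define a two-parent pedigree
#'
#' @param founders character(2): father and mother sample ids.
#' @param children character vector of child sample ids.
#' @return list of class `Pedigree`.
#' @export
pedigree <- function(founders, children) {
  stopifnot(length(founders) == 2L, length(children) >= 1L)
  structure(list(founders = founders, children = children,
                 samples = c(founders, children)), class = "Pedigree")
}

#' Read a PED-format pedigree file
#'
#' Expects the usual six whitespace-separated columns (family, individual,
#' father, mother, sex, phenotype); founders have father/mother "0".
#' @param path PED file.
#' @return a `Pedigree` (single founder couple plus their children).
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  colnames(ped)[1:4] <- c("fam", "id", "father", "mother")
  kids <- ped[ped$father != "0" & ped$mother != "0", ]
  stopifnot(nrow(kids) >= 1L)
  fathers <- unique(kids$father); mothers <- unique(kids$mother)
  stopifnot(length(fathers) == 1L, length(mothers) == 1L)
  pedigree(c(fathers, mothers), kids$id)
}

#' Check one locus for pedigree concordance
#'
#' MODE A (no inheritance map): concordant iff there exists an assignment
#' of each parent's two alleles to haplotypes and a per-child transmission
#' choice reproducing every child's genotype, decided by exhaustive search.
#' MODE B (`inheritance` given): transmissions are fixed; only parental
#' phasings are searched.
#'
#' @param genotypes named list sample -> integer pair of allele labels
#'   (e.g. c(0, 1)); NULL for a missing genotype.
#' @param ped a `Pedigree`.
#' @param inheritance optional named list child -> c(f, m), each 1 or 2:
#'   which paternal/maternal haplotype the child received.
#' @return "concordant", "discordant" or "unevaluated".
#' @export
check_locus <- function(genotypes, ped, inheritance = NULL) {
  gts <- genotypes[ped$samples]
  if (any(vapply(gts, is.null, logical(1)))) return("unevaluated")
  fa <- sort(genotypes[[ped$founders[1]]])
  mo <- sort(genotypes[[ped$founders[2]]])
  phasings <- function(g) unique(list(c(g[1], g[2]), c(g[2], g[1])))
  for (fp in phasings(fa)) for (mp in phasings(mo)) {
    ok <- TRUE
    for (ch in ped$children) {
      cg <- sort(genotypes[[ch]])
      if (is.null(inheritance)) {
        found <- FALSE
        for (ft in 1:2) for (mt in 1:2) {
          if (identical(sort(c(fp[ft], mp[mt])), cg)) found <- TRUE
        }
      } else {
        tr <- inheritance[[ch]]
        found <- identical(sort(c(fp[tr[1]], mp[tr[2]])), cg)
      }
      if (!found) { ok <- FALSE; break }
    }
    if (ok) return("concordant")
  }
  "discordant"
}

#' Summarize concordance verdicts under a GQ filter
#'
#' Loci where any sample's GQ falls below `min_gq` are excluded from the
#' evaluated set; `min_gq = 0` reproduces the unfiltered totals.
#'
#' @param verdicts character vector from [check_locus()].
#' @param gq numeric matrix (loci x samples) of genotype qualities.
#' @param min_gq minimum GQ required in all samples (default 0).
#' @return list of class `ConcordanceResult`: per-locus verdicts after
#'   filtering, concordant/evaluated counts and the proportion (NA when
#'   nothing is evaluated).
#' @export
summarize_concordance <- function(verdicts, gq = NULL, min_gq = 0L) {
  pass <- if (is.null(gq)) rep(TRUE, length(verdicts)) else
    apply(gq, 1L, function(x) all(!is.na(x) & x >= min_gq))
  eval_mask <- pass & verdicts != "unevaluated"
  conc <- sum(verdicts[eval_mask] == "concordant")
  evaluated <- sum(eval_mask)
  structure(list(
    verdicts = ifelse(pass, verdicts, "unevaluated"),
    concordant = conc, evaluated = evaluated,
    proportion = if (evaluated > 0L) conc / evaluated else NA_real_,
    min_gq = min_gq), class = "ConcordanceResult")
}

## Parse a VCF GT string into an integer allele pair (NULL when missing).
parse_gt <- function(gt) {
  if (is.na(gt) || grepl("\\.", gt)) return(NULL)
  as.integer(strsplit(gt, "[/|]")[[1]])
}

#' Evaluate pedigree concordance of a multi-sample SV VCF
#'
#' @param vcf_df result of [read_vcf()] with GT/GQ columns for all
#'   pedigree samples.
#' @param ped a `Pedigree`.
#' @param min_gq GQ filter applied via [summarize_concordance()].
#' @param inheritance optional MODE B map (see [check_locus()]).
#' @return a `ConcordanceResult` with the per-locus verdicts.
#' @export
concordance_from_vcf <- function(vcf_df, ped, min_gq = 0L,
                                 inheritance = NULL) {
  n <- nrow(vcf_df)
  verdicts <- character(n)
  gq <- matrix(NA_real_, n, length(ped$samples),
               dimnames = list(NULL, ped$samples))
  for (i in seq_len(n)) {
    gts <- lapply(ped$samples, function(s)
      parse_gt(vcf_df[[paste0("GT_", s)]][i]))
    names(gts) <- ped$samples
    verdicts[i] <- check_locus(gts, ped, inheritance)
    gq[i, ] <- vapply(ped$samples, function(s) {
      v <- vcf_df[[paste0("GQ_", s)]][i]
      if (is.null(v)) NA_real_ else as.numeric(v)
    }, numeric(1))
  }
  summarize_concordance(verdicts, gq, min_gq)
}
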