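## Comparison of called loci against a simulated truth table: recall,
## basepair-exact breakpoint fraction and genotype accuracy.

vcf_gt_dosage <- function(gt) {
  g <- parse_gt(gt)
  if (is.null(g)) return(NA_integer_)
  sum(g != 0L)
}

#' Evaluate called SVs against a planted truth table
#'
#' Truth and calls are matched by compatible type (tandem duplications may
#' be reported as insertions and vice versa), position within `tol` and
#' size ratio >= 0.5. Basepair exactness compares the canonical (leftmost)
#' truth coordinates and exact |svlen|; it is reported over non-repeat
#' placements, where a unique canonical position exists. Genotype accuracy
#' compares allele dosage per sample over matched loci.
#'
#' @param vcf_df result of [read_vcf()].
#' @param truth truth data.frame from [plant_svs()] / [simulate_dataset()].
#' @param samples sample ids to score genotypes for.
#' @param tol matching tolerance in bp (default 500).
#' @return list(recall, bp_exact, gt_accuracy, n_truth, matched = logical
#'   vector per truth row, detail = data.frame).
#' @export
evaluate_calls <- function(vcf_df, truth, samples, tol = 500L) {
  calls <- vcf_df[vcf_df$svtype %in% c("DEL", "INS", "DUP", "INV"), ,
                  drop = FALSE]
  n <- nrow(truth)
  matched <- logical(n)
  bp_exact <- rep(NA, n)
  gt_ok <- matrix(NA, n, length(samples), dimnames = list(NULL, samples))
  call_pos0 <- calls$pos  # POS (1-based anchor) equals 0-based breakpoint
  call_size <- abs(calls$svlen)
  for (i in seq_len(n)) {
    tt <- truth$type[i]
    compat <- if (tt %in% c("INS", "DUP")) c("INS", "DUP") else tt
    cand <- which(calls$svtype %in% compat &
                    calls$contig == truth$contig[i] &
                    abs(call_pos0 - truth$pos[i]) <= tol + truth$size[i] &
                    pmin(call_size, truth$size[i]) /
                      pmax(call_size, truth$size[i]) >= 0.5)
    if (length(cand) == 0L) next
    j <- cand[which.min(abs(call_pos0[cand] - truth$canonical_pos[i]))]
    matched[i] <- TRUE
    exact_pos <- call_pos0[j] == truth$canonical_pos[i]
    exact_size <- call_size[j] == truth$size[i]
    bp_exact[i] <- exact_pos && exact_size
    for (s in samples) {
      d_call <- vcf_gt_dosage(calls[[paste0("GT_", s)]][j])
      d_true <- truth[[paste0("gt_", s)]][i]
      gt_ok[i, s] <- !is.na(d_call) && d_call == d_true
    }
  }
  nonrep <- !truth$in_repeat
  detail <- data.frame(type = truth$type, size = truth$size,
                       pos = truth$pos, in_repeat = truth$in_repeat,
                       matched = matched, bp_exact = bp_exact)
  list(recall = mean(matched),
       bp_exact = if (any(matched & nonrep))
         mean(bp_exact[matched & nonrep]) else NA_real_,
       gt_accuracy = mean(gt_ok[matched, , drop = FALSE], na.rm = TRUE),
       n_truth = n, matched = matched, detail = detail)
}
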