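## Single-linkage clustering of signatures into candidate SV loci.

#' Cluster SV signatures into candidate loci
#'
#' Single-linkage clustering per contig. Two INDEL signatures link iff they
#' are the same kind, their positions differ by at most `max_dist`, and
#' min(size)/max(size) >= `size_ratio`. Two SPLIT_JUNCTION signatures link
#' iff both breakends lie within `max_dist` and orientations match.
#' SOFTCLIP signatures never seed clusters on their own; they are attached
#' to a cluster of other kinds when within `max_dist` of its span.
#' Clusters supported by fewer than `min_cluster_support` distinct reads
#' are dropped. Clusters are reported position-sorted with dense IDs from 0.
#'
#' @param sigs signature data.frame (see [scan_signatures()]).
#' @param max_dist maximum breakpoint distance to link (default 500).
#' @param size_ratio minimum size ratio to link indels (default 0.5).
#' @param min_cluster_support minimum distinct supporting reads (default 2).
#' @return list of `SignatureCluster` objects: list(cluster_id, contig,
#'   span = c(start, end), members = data.frame, kind_profile, sample_id).
#' @export
cluster_signatures <- function(sigs, max_dist = 500L, size_ratio = 0.5,
                               min_cluster_support = 2L) {
  if (nrow(sigs) == 0L) return(list())
  seeds <- sigs[sigs$kind != "SOFTCLIP", , drop = FALSE]
  clips <- sigs[sigs$kind == "SOFTCLIP", , drop = FALSE]
  clusters <- list()
  for (contig in unique(seeds$contig)) {
    sub <- seeds[seeds$contig == contig, , drop = FALSE]
    sub <- sub[order(sub$pos, sub$size, sub$read_id), , drop = FALSE]
    n <- nrow(sub)
    if (n == 0L) next
    parent <- uf_new(n)
    for (i in seq_len(n)) {
      j <- i + 1L
      while (j <= n && sub$pos[j] - sub$pos[i] <= max_dist) {
        if (signatures_link(sub, i, j, max_dist, size_ratio)) {
          parent <- uf_union(parent, i, j)
        }
        j <- j + 1L
      }
    }
    comp <- uf_components(parent)
    for (cid in unique(comp)) {
      members <- sub[comp == cid, , drop = FALSE]
      clusters[[length(clusters) + 1L]] <- list(contig = contig,
                                                members = members)
    }
  }
  ## attach soft clips to the nearest qualifying cluster
  if (nrow(clips) > 0L && length(clusters) > 0L) {
    for (r in seq_len(nrow(clips))) {
      best <- NA_integer_; best_d <- Inf
      for (ci in seq_along(clusters)) {
        cl <- clusters[[ci]]
        if (cl$contig != clips$contig[r]) next
        span <- range(cl$members$pos)
        d <- max(0L, span[1] - clips$pos[r], clips$pos[r] - span[2])
        if (d <= max_dist && d < best_d) { best <- ci; best_d <- d }
      }
      if (!is.na(best)) {
        clusters[[best]]$members <- rbind(clusters[[best]]$members,
                                          clips[r, , drop = FALSE])
      }
    }
  }
  ## support filter, span computation, canonical order and dense IDs
  out <- list()
  for (cl in clusters) {
    m <- cl$members
    support <- length(unique(m$read_id[m$kind != "SOFTCLIP"]))
    if (support < min_cluster_support) next
    ## span envelope; deletions extend to pos + size so the anchor window
    ## covers the full reference footprint of the event
    ext <- m$pos + ifelse(m$kind == "INDEL_DEL", m$size, 0L)
    out[[length(out) + 1L]] <- structure(list(
      cluster_id = NA_integer_, contig = cl$contig,
      span = c(start = min(m$pos), end = max(ext)),
      members = m[order(m$pos, m$size, m$read_id), , drop = FALSE],
      kind_profile = table(m$kind),
      sample_id = m$sample_id[1]), class = "SignatureCluster")
  }
  if (length(out) == 0L) return(out)
  ord <- order(vapply(out, function(x) x$contig, character(1)),
               vapply(out, function(x) x$span[["start"]], integer(1)),
               vapply(out, function(x) x$span[["end"]], integer(1)))
  out <- out[ord]
  for (i in seq_along(out)) out[[i]]$cluster_id <- i - 1L
  out
}

## Pairwise link predicate between two signature rows of one contig.
signatures_link <- function(sub, i, j, max_dist, size_ratio) {
  if (sub$kind[i] != sub$kind[j]) return(FALSE)
  if (abs(sub$pos[i] - sub$pos[j]) > max_dist) return(FALSE)
  k <- sub$kind[i]
  if (k %in% c("INDEL_DEL", "INDEL_INS")) {
    smin <- min(sub$size[i], sub$size[j]); smax <- max(sub$size[i], sub$size[j])
    return(smax == 0L || smin / smax >= size_ratio)
  }
  if (k == "SPLIT_JUNCTION") {
    return(identical(sub$orient[i], sub$orient[j]) &&
             identical(sub$mate_orient[i], sub$mate_orient[j]) &&
             identical(sub$mate_contig[i], sub$mate_contig[j]) &&
             !is.na(sub$mate_pos[i]) && !is.na(sub$mate_pos[j]) &&
             abs(sub$mate_pos[i] - sub$mate_pos[j]) <= max_dist)
  }
  FALSE
}
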