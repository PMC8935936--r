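# Candidate target scanning: ungapped seed-and-extend local alignment of
# a mobile cluster's consensus sequence against the receptor genome
# (match +1, mismatch -2, no gaps), exclusion of repeat-annotated hits,
# and the coverage-weighted identity score used to rank candidates:
#   pident       = (aligned_length - n_mismatches) / aligned_length * 100
#   pident_final = pident * (aligned_length / cluster_length)

#' Genomic consensus sequence of a cluster
#'
#' The + strand genomic substring of the cluster interval on the
#' cluster's source genome.
#'
#' @param cluster One-row cluster data.frame (chrom, start, end).
#' @param genome Named character vector of chromosome sequences.
#' @return Character scalar.
#' @export
cluster_consensus <- function(cluster, genome) {
  ch <- cluster$chrom[1]
  if (!ch %in% names(genome)) stop("unknown chromosome ", ch)
  if (cluster$start[1] < 0 || cluster$end[1] > nchar(genome[[ch]])) {
    stop("cluster interval out of chromosome bounds")
  }
  substr(genome[[ch]], cluster$start[1] + 1L, cluster$end[1])
}

# Best-scoring ungapped segment of a +1/-2 match indicator vector
# (Kadane); ties go to the earliest, then longest, segment. Returns NULL
# when every position mismatches.
best_segment <- function(match_vec) {
  s <- ifelse(match_vec, 1, -2)
  best <- 0; best_i <- NA_integer_; best_j <- NA_integer_
  cur <- 0; cur_i <- 1L
  for (j in seq_along(s)) {
    if (cur <= 0) { cur <- 0; cur_i <- j }
    cur <- cur + s[j]
    if (cur > best || (cur == best && !is.na(best_i) &&
                       cur_i == best_i && j > best_j)) {
      best <- cur; best_i <- cur_i; best_j <- j
    }
  }
  if (is.na(best_i) || best <= 0) return(NULL)
  # trim flanking mismatches (optimal segments start/end on matches)
  while (!match_vec[best_i]) best_i <- best_i + 1L
  while (!match_vec[best_j]) best_j <- best_j - 1L
  list(score = best, qstart = best_i, qend = best_j,
       mismatches = sum(!match_vec[best_i:best_j]))
}

#' Scan a receptor genome for candidate target regions of a cluster
#'
#' Ungapped seed-and-extend local alignment on both strands: exact
#' `word_size`-mers seed diagonals, each diagonal is scored with +1 per
#' match and -2 per mismatch, and the best segment per diagonal is kept.
#' Hits scoring below `min_score` and hits overlapping repeat intervals
#' are discarded; survivors are ranked by `pident_final` (descending,
#' deterministic tie-breaks).
#'
#' @param query Cluster consensus sequence (>= 9 nt).
#' @param genome Named character vector (receptor genome).
#' @param repeats Repeat interval data.frame (chrom, start, end) or NULL.
#' @param min_score Minimum segment score (default 14, about a 14-nt
#'   perfect seed).
#' @param keep_top Maximum number of hits returned.
#' @param word_size Seed word length (default 7, short-query blast
#'   convention).
#' @return data.frame: chrom, start, end, strand, aligned_length,
#'   n_mismatches, score, pident, pident_final, cluster_length.
#' @export
scan_targets <- function(query, genome, repeats = NULL, min_score = 14L,
                         keep_top = 25L, word_size = 7L) {
  if (is.null(genome) || length(genome) == 0 || all(nchar(genome) == 0)) {
    stop_arg("genome must be non-empty")
  }
  L <- nchar(query)
  if (L < 9) stop_arg("query must be >= 9 nt")
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      aligned_length = integer(), n_mismatches = integer(),
                      score = integer(), pident = numeric(),
                      pident_final = numeric(), cluster_length = integer(),
                      stringsAsFactors = FALSE)
  queries <- c(`+` = query, `-` = revcomp(query))
  hits <- list()
  for (str in c("+", "-")) {
    q <- queries[[str]]
    qchars <- strsplit(q, "")[[1]]
    words <- substring(q, seq_len(L - word_size + 1L),
                       seq_len(L - word_size + 1L) + word_size - 1L)
    uw <- unique(words[!grepl("[^ACGT]", words)])
    if (!length(uw)) next
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(uw))
    word_qpos <- split(seq_along(words), words)
    for (ch in names(genome)) {
      subj <- Biostrings::DNAString(genome[[ch]])
      glen <- nchar(genome[[ch]])
      m <- Biostrings::matchPDict(pd, subj)
      st <- Biostrings::startIndex(m)
      diags <- integer()
      for (wi in seq_along(uw)) {
        gpos <- st[[wi]]
        if (is.null(gpos) || !length(gpos)) next
        qpos <- word_qpos[[uw[wi]]]
        # diagonal d: query position 1 aligns to genome position d + 1
        diags <- c(diags, as.vector(outer(gpos, qpos, "-")))
      }
      diags <- unique(diags)
      for (d in diags) {
        qlo <- max(1L, 1L - d)
        qhi <- min(L, glen - d)
        if (qhi - qlo + 1L < word_size) next
        gseg <- substring(genome[[ch]], d + qlo, d + qhi)
        mv <- strsplit(gseg, "")[[1]] == qchars[qlo:qhi]
        seg <- best_segment(mv)
        if (is.null(seg) || seg$score < min_score) next
        g1 <- d + qlo + seg$qstart - 1L   # 1-based genome start
        g2 <- d + qlo + seg$qend - 1L
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = ch, start = g1 - 1L, end = g2, strand = str,
          aligned_length = seg$qend - seg$qstart + 1L,
          n_mismatches = seg$mismatches, score = seg$score,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) return(empty)
  out <- unique(do.call(rbind, hits))
  if (!is.null(repeats) && nrow(repeats)) {
    out <- out[!overlaps_any(out, repeats), , drop = FALSE]
  }
  if (nrow(out) == 0) return(empty)
  out$pident <- (out$aligned_length - out$n_mismatches) /
    out$aligned_length * 100
  out$pident_final <- out$pident * out$aligned_length / L
  out$cluster_length <- L
  out <- out[order(-out$pident_final, -out$score, out$chrom, out$start,
                   out$strand), , drop = FALSE]
  if (nrow(out) > keep_top) out <- out[seq_len(keep_top), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan targets for every cluster in a set
#'
#' @param cluster_set A `cluster_set` (e.g. mobile clusters on the donor
#'   genome).
#' @param source_genome Genome the clusters live on (consensus source).
#' @param receptor_genome Genome scanned for targets.
#' @param repeats Repeat intervals on the receptor genome, excluded from
#'   hits.
#' @param ... Passed to [scan_targets()].
#' @return data.frame of hits with a `cluster_id` column.
#' @export
scan_targets_set <- function(cluster_set, source_genome, receptor_genome,
                             repeats = NULL, ...) {
  cl <- cluster_set$clusters
  res <- lapply(seq_len(nrow(cl)), function(i) {
    cons <- cluster_consensus(cl[i, ], source_genome)
    if (nchar(cons) < 9) return(NULL)
    h <- scan_targets(cons, receptor_genome, repeats, ...)
    if (nrow(h)) cbind(cluster_id = cl$id[i], h, stringsAsFactors = FALSE)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) {
    return(data.frame(cluster_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), aligned_length = integer(),
                      n_mismatches = integer(), score = integer(),
                      pident = numeric(), pident_final = numeric(),
                      cluster_length = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
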