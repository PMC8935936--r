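# Independent brute-force oracles. These deliberately avoid the code
# paths (and the libraries) backing the implementation: plain character
# scans, per-base tabulation, pairwise loops, closed-form hypergeometric
# sums.

oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# all exact occurrences of `read` in `genome` (named character), both
# strands; O(n*m) substring scan
oracle_occurrences <- function(genome, read) {
  out <- NULL
  rc <- oracle_revcomp(read)
  m <- nchar(read)
  for (ch in names(genome)) {
    g <- genome[[ch]]
    for (i in seq_len(max(nchar(g) - m + 1L, 0L))) {
      sub <- substr(g, i, i + m - 1L)
      if (sub == read) {
        out <- rbind(out, data.frame(chrom = ch, start = i - 1L,
                                     end = i + m - 1L, strand = "+"))
      }
      if (sub == rc) {
        out <- rbind(out, data.frame(chrom = ch, start = i - 1L,
                                     end = i + m - 1L, strand = "-"))
      }
    }
  }
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character())
  }
  out[order(out$chrom, out$start, out$strand), , drop = FALSE]
}

# maximal runs of per-base depth >= mincov, by explicit tabulation
oracle_islands <- function(placements, chrom, mincov, chrom_len) {
  depth <- integer(chrom_len)
  p <- placements[placements$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(p))) {
    rng <- (p$start[i] + 1L):p$end[i]
    depth[rng] <- depth[rng] + 1L
  }
  ok <- depth >= mincov
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(chrom = rep(chrom, sum(keep)), start = starts[keep] - 1L,
             end = ends[keep])
}

# transitive closure merge: repeatedly merge any pair with gap <= pad
oracle_merge <- function(islands, pad) {
  iv <- islands[order(islands$start), c("start", "end")]
  repeat {
    merged_any <- FALSE
    i <- 1
    while (i < nrow(iv)) {
      if (iv$start[i + 1] - iv$end[i] <= pad) {
        iv$end[i] <- max(iv$end[i], iv$end[i + 1])
        iv <- iv[-(i + 1), , drop = FALSE]
        merged_any <- TRUE
      } else i <- i + 1
    }
    if (!merged_any) break
  }
  data.frame(chrom = islands$chrom[1], start = iv$start, end = iv$end,
             row.names = NULL)
}

# does interval a overlap (>= 1 bp) any interval of b? pairwise loop
oracle_overlaps_any <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & b$start < a$end[i] & b$end > a$start[i])
  }, logical(1))
}

# upper-tail hypergeometric P(X >= a) by dhyper sum:
# K term genes among N background, n foreground draws
oracle_hyper_tail <- function(a, K, n, N) {
  ks <- a:min(K, n)
  sum(vapply(ks, function(k) {
    choose(K, k) * choose(N - K, n - k) / choose(N, n)
  }, numeric(1)))
}

# brute-force 3' adapter trim: earliest i where the read suffix matches
# an adapter prefix of length >= min_overlap (or the full adapter fits
# internally)
oracle_trim <- function(read, adapter, min_overlap) {
  n <- nchar(read); alen <- nchar(adapter)
  for (i in seq_len(n)) {
    k <- min(n - i + 1L, alen)
    if (k < min_overlap) break
    if (substr(read, i, i + k - 1L) == substr(adapter, 1L, k)) {
      return(substr(read, 1L, i - 1L))
    }
  }
  read
}

oracle_entropy <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  p <- table(factor(ch, levels = c("A", "C", "G", "T"))) / length(ch)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# best ungapped local segment (+1 match, -2 mismatch) between query and
# every diagonal of genome, both strands, by exhaustive (i, j) scoring
oracle_best_hits <- function(query, genome, min_score) {
  hits <- NULL
  for (str in c("+", "-")) {
    q <- if (str == "+") query else oracle_revcomp(query)
    qc <- strsplit(q, "")[[1]]
    L <- length(qc)
    for (ch in names(genome)) {
      gc <- strsplit(genome[[ch]], "")[[1]]
      G <- length(gc)
      for (d in (1 - L):(G - 1)) {
        qlo <- max(1L, 1L - d); qhi <- min(L, G - d)
        if (qhi < qlo) next
        s <- ifelse(gc[(d + qlo):(d + qhi)] == qc[qlo:qhi], 1, -2)
        best <- -Inf; bi <- NA; bj <- NA
        for (i in seq_along(s)) {
          acc <- 0
          for (j in i:length(s)) {
            acc <- acc + s[j]
            if (acc > best) { best <- acc; bi <- i; bj <- j }
          }
        }
        if (is.finite(best) && best >= min_score) {
          g1 <- d + qlo + bi - 1L
          hits <- rbind(hits, data.frame(
            chrom = ch, start = g1 - 1L, end = d + qlo + bj - 1L,
            strand = str, score = best))
        }
      }
    }
  }
  hits
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
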