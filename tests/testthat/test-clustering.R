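# Cluster calling: coverage islands, pad merging, dicer call, size
# class, known-miRNA matching, monotonicity properties.

mk_plc <- function(starts, width = 24L, chrom = "chr1",
                   replicate = "rep1") {
  data.frame(read_id = sprintf("r%04d", seq_along(starts)), chrom = chrom,
             start = as.integer(starts), end = as.integer(starts + width),
             strand = "+", n_occurrences = 1L, replicate = replicate,
             stringsAsFactors = FALSE)
}

test_that("islands appear exactly where depth reaches mincov", {
  # 5 identical reads -> one island over the read footprint
  p <- mk_plc(rep(100, 5))
  isl <- find_islands(p, "chr1", 5)
  expect_equal(isl$start, 100)
  expect_equal(isl$end, 124)
  # 4 identical reads -> none
  expect_equal(nrow(find_islands(mk_plc(rep(100, 4)), "chr1", 5)), 0)
  # staggered reads: island spans exactly the >= mincov positions
  p2 <- mk_plc(c(100, 101, 102, 103, 104), width = 5)
  isl2 <- find_islands(p2, "chr1", 5)
  want <- oracle_islands(p2, "chr1", 5, 200)
  expect_equal(isl2$start, want$start)
  expect_equal(isl2$end, want$end)
  expect_equal(isl2$start, 104)  # depth profile ramps 1..5..1
  expect_equal(isl2$end, 105)
})

test_that("island finding equals per-base tabulation on random placements", {
  set.seed(303)
  for (rep_ in 1:60) {
    n <- sample(5:60, 1)
    p <- mk_plc(sample(0:400, n, replace = TRUE),
                width = sample(18:26, 1))
    mincov <- sample(2:6, 1)
    got <- find_islands(p, "chr1", mincov)
    want <- oracle_islands(p, "chr1", mincov, 500)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("pad merging is inclusive at the boundary and transitive", {
  isl <- data.frame(chrom = "chr1", start = c(0L, 124L), end = c(24L, 148L))
  # gap = 100 -> merged
  expect_equal(nrow(merge_islands(isl, 100)), 1)
  # gap = 101
  isl2 <- data.frame(chrom = "chr1", start = c(0L, 125L), end = c(24L, 149L))
  expect_equal(nrow(merge_islands(isl2, 100)), 2)
  # chain with gaps 50 and 100 merges into one
  isl3 <- data.frame(chrom = "chr1", start = c(0L, 74L, 198L),
                     end = c(24L, 98L, 222L))
  m <- merge_islands(isl3, 100)
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 0)
  expect_equal(m$end, 222)
  # random instances vs transitive-closure oracle
  set.seed(304)
  for (i in 1:60) {
    k <- sample(2:12, 1)
    s <- sort(sample(0:2000, k))
    e <- s + sample(10:60, k, replace = TRUE)
    # make non-overlapping
    for (j in seq_len(k - 1)) if (e[j] > s[j + 1]) e[j] <- s[j + 1]
    iv <- data.frame(chrom = "chr1", start = s, end = e)
    iv <- iv[iv$start < iv$end, ]
    if (nrow(iv) < 2) next
    pad <- sample(0:150, 1)
    got <- merge_islands(iv, pad)
    want <- oracle_merge(iv, pad)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("clusters carry consistent histograms and extend to their reads", {
  p <- rbind(mk_plc(rep(100, 6), width = 24, replicate = "rep1"),
             mk_plc(rep(103, 4), width = 21, replicate = "rep2"))
  p$read_id <- sprintf("r%04d", seq_len(nrow(p)))
  cs <- build_clusters(p, cluster_params())
  expect_equal(nrow(cs$clusters), 1)
  cl <- cs$clusters[1, ]
  expect_equal(cl$reads_total, 10)
  expect_equal(cl$start, 100)
  expect_equal(cl$end, 124)
  expect_equal(sum(cl$reads_by_length[[1]]), cl$reads_total)
  expect_equal(sum(cl$reads_by_replicate[[1]]), cl$reads_total)
  expect_equal(unname(cl$reads_by_length[[1]]["21"]), 4L)
  expect_equal(unname(cl$reads_by_replicate[[1]]["rep2"]), 4L)
  expect_equal(cl$rpm, 10 / 10 * 1e6)
  # empty placements -> empty cluster set
  expect_equal(nrow(build_clusters(p[0, ])$clusters), 0)
})

test_that("every placement in a covered region is assigned to exactly one cluster", {
  sc <- tiny_scenario(seed = 91, mobile_fraction = 0, n_reads = 3000)
  reads <- clean_reads(sc)
  mp <- map_readset(build_index(sc$pair$receptor), reads,
                    map_params("random_one", 2))
  cs <- build_clusters(mp$placements)
  expect_equal(anyDuplicated(cs$assignments$read_id), 0)
  expect_equal(sum(cs$clusters$reads_total), nrow(cs$assignments))
})

test_that("dicer call is inclusive at 80% and size class ties go to the larger length", {
  # 8 of 10 in range at exactly 0.8
  p <- rbind(mk_plc(rep(100, 8), width = 24),
             mk_plc(rep(100, 2), width = 19))
  p$read_id <- sprintf("r%04d", seq_len(nrow(p)))
  cs <- call_dicer(build_clusters(p))
  expect_true(cs$clusters$dicer_call[1])
  expect_equal(cs$clusters$size_class[1], 24)
  # 7 of 10 -> negative, size class unset
  p2 <- rbind(mk_plc(rep(100, 7), width = 24),
              mk_plc(rep(100, 3), width = 19))
  p2$read_id <- sprintf("r%04d", seq_len(nrow(p2)))
  cs2 <- call_dicer(build_clusters(p2))
  expect_false(cs2$clusters$dicer_call[1])
  expect_true(is.na(cs2$clusters$size_class[1]))
  # 5 x 21nt vs 5 x 24nt -> tie -> 24
  p3 <- rbind(mk_plc(rep(100, 5), width = 21),
              mk_plc(rep(100, 5), width = 24))
  p3$read_id <- sprintf("r%04d", seq_len(nrow(p3)))
  cs3 <- call_dicer(build_clusters(p3))
  expect_equal(cs3$clusters$size_class[1], 24)
})

test_that("raising mincov shrinks islands (nesting) and raising pad never splits clusters", {
  set.seed(305)
  p <- mk_plc(sample(0:1000, 300, replace = TRUE), width = 22)
  # islands at a higher mincov are nested inside those at a lower one
  # (their count may rise through splitting, but never their extent)
  prev <- find_islands(p, "chr1", 1)
  for (mc in 2:8) {
    cur <- find_islands(p, "chr1", mc)
    if (nrow(cur)) {
      inside <- oracle_overlaps_any(cur, prev)
      expect_true(all(inside))
      covered <- function(x) sum(x$end - x$start)
      expect_lte(covered(cur), covered(prev))
    }
    prev <- cur
  }
  isl <- find_islands(p, "chr1", 3)
  n_merged <- vapply(c(0, 10, 50, 100, 200), function(pad) {
    nrow(merge_islands(isl, pad))
  }, integer(1))
  expect_true(all(diff(n_merged) <= 0))
})

test_that("cluster calling recovers well-separated planted loci one-to-one", {
  sc <- tiny_scenario(seed = 92, mobile_fraction = 0, n_reads = 4000)
  reads <- clean_reads(sc)
  mp <- map_readset(build_index(sc$pair$receptor), reads,
                    map_params("random_one", 2))
  cs <- build_clusters(mp$placements)
  expect_equal(nrow(cs$clusters), nrow(sc$loci))
  # each cluster overlaps exactly one planted locus
  ov <- mapply(function(ch, s, e) {
    sum(sc$loci$chrom == ch & sc$loci$start < e & sc$loci$end > s)
  }, cs$clusters$chrom, cs$clusters$start, cs$clusters$end)
  expect_true(all(ov == 1))
})

test_that("known-miRNA matching follows the Hamming-window rule", {
  set.seed(306)
  hp <- c(mir1 = random_seq(90), mir2 = random_seq(90))
  mature <- substr(hp[["mir1"]], 20, 40)  # 21 nt
  mk_cs <- function(seqs) {
    reads <- data.frame(id = sprintf("r%02d", seq_along(seqs)),
                        sequence = seqs, replicate = "rep1")
    p <- data.frame(read_id = reads$id, chrom = "chr1", start = 100L,
                    end = 100L + nchar(seqs), strand = "+",
                    n_occurrences = 1L, replicate = "rep1")
    list(cs = build_clusters(p, cluster_params(mincov = 1)), reads = reads)
  }
  # exact hairpin substring -> matched
  x <- mk_cs(rep(mature, 5))
  m <- match_known_mirna(x$cs, x$reads, hp)
  expect_identical(m$clusters$mirna_match[1], "mir1")
  # 2 mismatches -> matched; 3 -> not
  mut <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    for (p in seq_len(k)) {
      ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    }
    paste(ch, collapse = "")
  }
  x2 <- mk_cs(rep(mut(mature, 2), 5))
  expect_identical(match_known_mirna(x2$cs, x2$reads, hp)$clusters$mirna_match[1],
                   "mir1")
  x3 <- mk_cs(rep(mut(mature, 3), 5))
  expect_true(is.na(match_known_mirna(x3$cs, x3$reads, hp)$clusters$mirna_match[1]))
  # unrelated read sharing no window -> no match
  x4 <- mk_cs(rep(random_seq(21), 5))
  best <- min(vapply(hp, function(h) {
    # sliding-window Hamming oracle
    m <- nchar(x4$reads$sequence[1])
    min(vapply(seq_len(nchar(h) - m + 1), function(i) {
      sum(strsplit(substr(h, i, i + m - 1), "")[[1]] !=
            strsplit(x4$reads$sequence[1], "")[[1]])
    }, numeric(1)))
  }, numeric(1)))
  got <- match_known_mirna(x4$cs, x4$reads, hp)$clusters$mirna_match[1]
  expect_identical(is.na(got), best > 2)
})

test_that("cluster building is deterministic for fixed placements and params", {
  sc <- tiny_scenario(seed = 93, n_reads = 1500)
  reads <- clean_reads(sc)
  mp <- map_readset(build_index(sc$pair$receptor), reads,
                    map_params("random_one", 4))
  a <- call_dicer(build_clusters(mp$placements))
  b <- call_dicer(build_clusters(mp$placements))
  expect_identical(a$clusters, b$clusters)
})
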