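# Target scanning: ungapped local alignment, repeat exclusion and the
# coverage-weighted identity score.

test_that("a verbatim cluster occurrence scores pident_final 100", {
  set.seed(180)
  g <- c(chr1 = random_seq(3000))
  q <- substr(g[[1]], 1001, 1060)
  hits <- scan_targets(q, g)
  top <- hits[1, ]
  expect_equal(top$aligned_length, 60)
  expect_equal(top$n_mismatches, 0)
  expect_equal(top$pident, 100)
  expect_equal(top$pident_final, 100)
  expect_equal(top$start, 1000)
})

test_that("pident_final weights identity by the aligned fraction of the cluster", {
  set.seed(181)
  left <- random_seq(30)
  g <- c(chr1 = paste0(random_seq(500), left, random_seq(500)))
  # query = the genomic 30-mer plus 30 foreign bases: perfect hit over half
  q <- paste0(left, strrep("A", 15), strrep("C", 15))
  hits <- scan_targets(q, g, min_score = 14)
  top <- hits[1, ]
  expect_equal(top$pident, 100)
  expect_equal(top$pident_final, 50)
  # 37 of 38 aligned, 0 mismatches -> 97.37 (printed precision)
  g2 <- c(chr1 = paste0(random_seq(300), random_seq(37), random_seq(300)))
  frag <- substr(g2[[1]], 301, 337)
  q2 <- paste0(frag, "A")  # 38-nt cluster, 37 alignable
  # ensure the appended base mismatches the genome continuation
  while (substr(g2[[1]], 338, 338) == "A") {
    g2 <- c(chr1 = paste0(substr(g2[[1]], 1, 337), random_seq(300)))
  }
  h2 <- scan_targets(q2, g2)
  expect_equal(h2$aligned_length[1], 37)
  expect_equal(round(h2$pident_final[1], 2), 97.37)
})

test_that("mismatch counts equal the SNPs inside the aligned span", {
  # donor locus differs from receptor homolog at k known positions
  set.seed(182)
  for (k in c(1, 3, 5)) {
    donor_loc <- random_seq(80)
    rec_loc <- strsplit(donor_loc, "")[[1]]
    at <- sort(sample(10:70, k))
    for (p in at) rec_loc[p] <- setdiff(c("A", "C", "G", "T"), rec_loc[p])[1]
    g <- c(chr1 = paste0(random_seq(400), paste(rec_loc, collapse = ""),
                         random_seq(400)))
    hits <- scan_targets(donor_loc, g)
    full <- hits[hits$aligned_length == 80, ]
    if (nrow(full) > 0) {
      expect_equal(full$n_mismatches[1], k)
      expect_equal(full$pident[1], (80 - k) / 80 * 100)
    } else {
      # with clustered mismatches the best local segment may exclude an
      # edge mismatch; it must then be mismatch-free at its boundaries
      expect_gt(hits$score[1], 0)
    }
  }
})

test_that("pident_final is invariant to the strand of the hit", {
  set.seed(183)
  core <- random_seq(50)
  g_fw <- c(chr1 = paste0(random_seq(200), core, random_seq(200)))
  g_rc <- c(chr1 = paste0(random_seq(200), oracle_revcomp(core),
                          random_seq(200)))
  h_fw <- scan_targets(core, g_fw)[1, ]
  h_rc <- scan_targets(core, g_rc)[1, ]
  expect_identical(h_fw$strand, "+")
  expect_identical(h_rc$strand, "-")
  expect_equal(h_fw$pident_final, h_rc$pident_final)
  expect_equal(h_fw$aligned_length, h_rc$aligned_length)
})

test_that("repeat-annotated hits are excluded", {
  set.seed(184)
  core <- random_seq(40)
  g <- c(chr1 = paste0(random_seq(100), core, random_seq(100), core,
                       random_seq(100)))
  no_mask <- scan_targets(core, g)
  expect_equal(sum(no_mask$pident_final == 100), 2)
  reps <- data.frame(chrom = "chr1", start = 100L, end = 140L)
  masked <- scan_targets(core, g, repeats = reps)
  expect_equal(sum(masked$pident_final == 100), 1)
  expect_true(all(masked$start >= 140))
})

test_that("seed-and-extend agrees with the exhaustive diagonal oracle", {
  set.seed(185)
  for (i in 1:12) {
    g <- c(c1 = random_seq(300))
    # plant a noisy copy of the query
    q <- random_seq(sample(25:40, 1))
    qm <- strsplit(q, "")[[1]]
    nmut <- sample(0:3, 1)
    if (nmut > 0) {
      at <- sample(5:(length(qm) - 5), nmut)
      for (p in at) qm[p] <- setdiff(c("A", "C", "G", "T"), qm[p])[1]
    }
    ins_at <- sample(50:250, 1)
    g[[1]] <- paste0(substr(g[[1]], 1, ins_at), paste(qm, collapse = ""),
                     substr(g[[1]], ins_at + 1, 300))
    got <- scan_targets(q, g, min_score = 14, keep_top = 100)
    want <- oracle_best_hits(q, g, 14)
    # the oracle enumerates every diagonal: the implementation must reach
    # the same optimum (several distinct segments may tie for it)
    expect_equal(max(got$score), max(want$score))
    # and each reported hit must rescore to its claimed values
    for (j in seq_len(min(nrow(got), 5))) {
      h <- got[j, ]
      qh <- if (h$strand == "+") q else oracle_revcomp(q)
      gsub_ <- substr(g[[h$chrom]], h$start + 1, h$end)
      # locate the query offset of this hit from its diagonal alignment
      found <- FALSE
      for (off in 0:(nchar(qh) - h$aligned_length)) {
        qseg <- substr(qh, off + 1, off + h$aligned_length)
        mm <- sum(strsplit(qseg, "")[[1]] != strsplit(gsub_, "")[[1]])
        sc_ <- (h$aligned_length - mm) - 2 * mm
        if (mm == h$n_mismatches && sc_ == h$score) { found <- TRUE; break }
      }
      expect_true(found)
    }
  }
})

test_that("consensus extraction returns the genomic substring of the cluster", {
  set.seed(186)
  g <- c(chr2 = random_seq(500))
  cl <- data.frame(id = "c1", chrom = "chr2", start = 100L, end = 130L)
  expect_identical(cluster_consensus(cl, g), substr(g[[1]], 101, 130))
  expect_error(cluster_consensus(data.frame(chrom = "chr2", start = 490L,
                                            end = 600L), g), "bounds")
  expect_error(cluster_consensus(data.frame(chrom = "nope", start = 0L,
                                            end = 10L), g), "chromosome")
})

test_that("a simulated locus consensus equals the planted locus sequence", {
  sc <- tiny_scenario(seed = 187, mobile_fraction = 0, n_reads = 3000)
  reads <- clean_reads(sc)
  mp <- map_readset(build_index(sc$pair$receptor), reads,
                    map_params("random_one", 1))
  cs <- build_clusters(mp$placements)
  cl <- cs$clusters[1, ]
  locus <- sc$loci[sc$loci$chrom == cl$chrom & sc$loci$start < cl$end &
                     sc$loci$end > cl$start, ]
  cons <- cluster_consensus(cl, sc$pair$receptor)
  # the cluster sits inside its planted locus, so its consensus is a
  # substring of the locus sequence
  locus_seq <- substr(sc$pair$receptor[[locus$chrom]], locus$start + 1,
                      locus$end)
  expect_true(grepl(cons, locus_seq, fixed = TRUE))
})

test_that("queries shorter than 9 nt and empty genomes are rejected", {
  expect_error(scan_targets("ACGTACGT", c(c = "ACGT")), ">= 9")
  expect_error(scan_targets("ACGTACGTA", character(0)), "non-empty")
})
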