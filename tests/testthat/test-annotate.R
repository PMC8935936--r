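# Annotation, co-localization, replicate statistics, depth categories,
# enrichment.

test_that("promoter derivation handles strands, clipping and empty promoters", {
  genes <- data.frame(chrom = "chr1",
                      start = c(5000L, 5000L, 0L),
                      end = c(6000L, 6000L, 400L),
                      strand = c("+", "-", "+"),
                      id = c("gp", "gm", "gz"))
  prom <- derive_promoters(genes, c(chr1 = 6500L))
  p1 <- prom[prom$id == "gp_prom", ]
  expect_equal(c(p1$start, p1$end), c(3000, 5000))
  p2 <- prom[prom$id == "gm_prom", ]
  expect_equal(c(p2$start, p2$end), c(6000, 6500))  # clipped
  expect_false("gz_prom" %in% prom$id)              # empty, omitted
})

test_that("cluster annotation uses 1-bp any-overlap with multiple labels", {
  genes <- data.frame(chrom = "chr1", start = 5000L, end = 6000L,
                      strand = "+", id = "g1")
  reps <- data.frame(chrom = "chr1", start = 8000L, end = 8500L,
                     strand = "+", id = "r1")
  ann <- feature_annotation(genes, reps)
  cl <- data.frame(id = c("in_gene", "straddle", "nowhere"),
                   chrom = "chr1",
                   start = c(5200L, 4950L, 9000L),
                   end = c(5300L, 5050L, 9100L))
  got <- annotate_clusters(cl, ann, c(chr1 = 20000L))
  expect_identical(got$label[got$cluster_id == "in_gene"], "gene_body")
  # straddling the 5' end hits gene body and the 2-kb promoter
  expect_identical(got$label[got$cluster_id == "straddle"],
                   "gene_body,promoter_2kb")
  expect_identical(got$label[got$cluster_id == "nowhere"], "intergenic")
})

test_that("planted 24-nt loci annotate to promoters/repeats, 21-nt to gene bodies", {
  sc <- tiny_scenario(seed = 150, mobile_fraction = 0, n_reads = 3000)
  reads <- clean_reads(sc)
  mp <- map_readset(build_index(sc$pair$receptor), reads,
                    map_params("random_one", 1))
  cs <- build_clusters(mp$placements)
  lens <- setNames(nchar(sc$pair$receptor), names(sc$pair$receptor))
  anno <- annotate_clusters(cs, sc$annotation, lens)
  cs <- call_dicer(cs)
  cl <- cs$clusters
  for (i in seq_len(nrow(cl))) {
    locus <- sc$loci[sc$loci$chrom == cl$chrom[i] &
                       sc$loci$start < cl$end[i] &
                       sc$loci$end > cl$start[i], ]
    lab <- anno[anno$cluster_id == cl$id[i], ]
    if (locus$locus_class == "siRNA24") {
      expect_true(lab$promoter_2kb || lab$repeat_el)
    } else if (locus$locus_class == "siRNA21") {
      expect_true(lab$gene_body)
    }
  }
})

test_that("co-localization matches the pairwise brute-force oracle", {
  # worked examples
  a <- data.frame(id = "a1", chrom = "chr1", start = 100L, end = 200L)
  b <- data.frame(id = "b1", chrom = "chr1", start = 199L, end = 300L)
  r <- co_localize(a, b)
  expect_equal(r$n_common_a, 1)  # 1-bp overlap counts
  expect_equal(co_localize(a, a)$pct_common_a, 100)
  disjoint <- data.frame(id = "b2", chrom = "chr1", start = 300L, end = 400L)
  expect_equal(co_localize(a, disjoint)$n_common_a, 0)
  # random interval sets
  set.seed(160)
  for (i in 1:60) {
    na <- sample(1:30, 1); nb <- sample(1:30, 1)
    mk <- function(n) {
      s <- sample(0:2000, n, replace = TRUE)
      data.frame(id = sprintf("x%02d", seq_len(n)),
                 chrom = sample(c("c1", "c2"), n, replace = TRUE),
                 start = s, end = s + sample(20:200, n, replace = TRUE))
    }
    A <- mk(na); B <- mk(nb)
    r <- co_localize(A, B)
    expect_identical(r$common_a, oracle_overlaps_any(A, B))
    expect_identical(r$common_b, oracle_overlaps_any(B, A))
    expect_equal(r$n_common_a + r$n_specific_a, na)
    expect_equal(r$n_common_b + r$n_specific_b, nb)
  }
})

test_that("replicate presence and CV follow the sample-sd formula", {
  mk_cs <- function(counts) {
    cl <- data.frame(id = "cl_00001", chrom = "chr1", start = 0L,
                     end = 100L, reads_total = sum(counts),
                     rpm = 0, dicer_call = NA, size_class = NA_integer_,
                     mirna_match = NA_character_)
    cl$reads_by_length <- list(c("21" = sum(counts)))
    cl$reads_by_replicate <- list(counts[counts > 0])
    structure(list(clusters = cl,
                   assignments = data.frame(read_id = character(),
                                            cluster_id = character()),
                   params = cluster_params(), total_mapped_reads = 1),
              class = "cluster_set")
  }
  s1 <- replicate_stats(mk_cs(c(rep1 = 5, rep2 = 5, rep3 = 5)), 3)
  expect_equal(s1$presence_count, 3)
  expect_equal(s1$cv, 0)
  s2 <- replicate_stats(mk_cs(c(rep1 = 10, rep2 = 20, rep3 = 30)), 3)
  expect_equal(s2$cv, 50)
  s3 <- replicate_stats(mk_cs(c(rep3 = 6)), 3)
  expect_equal(s3$presence_count, 1)
  expect_equal(round(s3$cv, 1), 173.2)
  expect_error(replicate_stats(mk_cs(c(rep1 = 1)), 1), "replicates")
})

test_that("depth categories partition clusters into the seven default bins", {
  cl <- data.frame(id = sprintf("c%d", 1:8), chrom = "chr1",
                   start = 0L, end = 10L,
                   reads_total = c(5L, 6L, 10L, 11L, 100L, 500L, 1000L, 1001L))
  h <- depth_categories(cl)
  expect_length(h, 7)
  expect_equal(sum(h), nrow(cl))
  expect_equal(unname(h["<=5"]), 1L)
  expect_equal(unname(h["6-10"]), 2L)   # 6 and 10
  expect_equal(unname(h["11-50"]), 1L)
  expect_equal(unname(h[">1000"]), 1L)
  expect_equal(sum(depth_categories(cl[0, ])), 0)
  expect_error(depth_categories(cl, c(10, 5)), "increasing")
})

test_that("enrichment p-values equal the closed-form hypergeometric tail", {
  # a term covering all background genes is never enriched
  bg <- sprintf("g%03d", 1:100)
  tm_all <- data.frame(term_id = "T_all", gene_id = bg)
  r <- enrichment_test(bg[1:10], bg, tm_all)
  expect_equal(r$p_value, 1)
  expect_false(r$significant)
  # fg = the 10 term genes out of 100, fg size 10: p = 1 / C(100, 10)
  tm <- data.frame(term_id = "T1", gene_id = bg[1:10])
  r2 <- enrichment_test(bg[1:10], bg, tm)
  expect_equal(r2$p_value, 1 / choose(100, 10), tolerance = 1e-12)
  # random instances vs dhyper-sum oracle
  set.seed(170)
  for (i in 1:60) {
    N <- sample(30:120, 1)
    bgx <- sprintf("g%03d", seq_len(N))
    n <- sample(5:20, 1)
    fg <- sample(bgx, n)
    K <- sample(3:25, 1)
    tmx <- data.frame(term_id = "T", gene_id = sample(bgx, K))
    a <- sum(fg %in% tmx$gene_id)
    got <- enrichment_test(fg, bgx, tmx)$p_value
    expect_equal(got, oracle_hyper_tail(a, K, n, N), tolerance = 1e-9)
  }
  expect_error(enrichment_test(character(0), bg, tm), "non-empty")
  expect_error(enrichment_test(c("zz"), bg, tm), "subset")
})
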