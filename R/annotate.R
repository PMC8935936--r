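# Genomic annotation of clusters (gene body / 2-kb promoter / repeat),
# cross-set co-localization, replicate-presence and CV statistics, depth
# categories, and Fisher-exact term enrichment.

#' Derive 2-kb promoter intervals from stranded genes
#'
#' The promoter of a + strand gene [s, e) is [max(0, s - width), s); of a
#' - strand gene, [e, e + width) clipped to the chromosome end. Empty
#' promoters (gene abutting the chromosome edge) are omitted.
#'
#' @param genes data.frame chrom, start, end, strand, id.
#' @param chrom_lengths Named integer vector of chromosome lengths; NULL
#'   leaves - strand promoters unclipped.
#' @param width Promoter width (nt), default 2000.
#' @return data.frame chrom, start, end, strand, id (ids suffixed
#'   "_prom").
#' @export
derive_promoters <- function(genes, chrom_lengths = NULL, width = 2000L) {
  if (is.null(genes) || nrow(genes) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      id = character(), stringsAsFactors = FALSE))
  }
  plus <- genes$strand == "+"
  start <- ifelse(plus, pmax(0L, genes$start - width), genes$end)
  end <- ifelse(plus, genes$start, genes$end + width)
  if (!is.null(chrom_lengths)) {
    end <- pmin(end, chrom_lengths[genes$chrom])
  }
  out <- data.frame(chrom = genes$chrom, start = as.integer(start),
                    end = as.integer(end), strand = genes$strand,
                    id = paste0(genes$id, "_prom"),
                    stringsAsFactors = FALSE)
  out <- out[out$start < out$end, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Any-overlap (>= 1 bp) between two 0-based half-open interval tables;
# returns logical vector: does each row of a overlap >= 1 row of b?
overlaps_any <- function(a, b) {
  if (nrow(a) == 0) return(logical(0))
  if (nrow(b) == 0) return(rep(FALSE, nrow(a)))
  hit <- rep(FALSE, nrow(a))
  for (ch in unique(a$chrom)) {
    ai <- which(a$chrom == ch)
    bi <- which(b$chrom == ch)
    if (!length(bi)) next
    ov <- IRanges::overlapsAny(
      IRanges::IRanges(a$start[ai] + 1L, a$end[ai]),
      IRanges::IRanges(b$start[bi] + 1L, b$end[bi]))
    hit[ai] <- ov
  }
  hit
}

#' Annotate clusters by genomic context
#'
#' Any overlap (>= 1 bp) with a gene body, 2-kb promoter or repeat
#' assigns the corresponding label; multiple labels are allowed; clusters
#' with no label are intergenic.
#'
#' @param clusters Cluster data.frame (id, chrom, start, end) or a
#'   `cluster_set`.
#' @param annotation A `feature_annotation`.
#' @param chrom_lengths Named vector for promoter clipping (optional).
#' @return data.frame cluster_id, gene_body, promoter_2kb, repeat_el
#'   (logicals), label (comma-joined, "intergenic" when none).
#' @export
annotate_clusters <- function(clusters, annotation, chrom_lengths = NULL) {
  if (inherits(clusters, "cluster_set")) clusters <- clusters$clusters
  promoters <- derive_promoters(annotation$genes, chrom_lengths)
  gb <- overlaps_any(clusters, annotation$genes)
  pr <- overlaps_any(clusters, promoters)
  rp <- overlaps_any(clusters, annotation$repeats)
  label <- vapply(seq_len(nrow(clusters)), function(i) {
    l <- c("gene_body", "promoter_2kb", "repeat")[c(gb[i], pr[i], rp[i])]
    if (length(l) == 0) "intergenic" else paste(l, collapse = ",")
  }, character(1))
  data.frame(cluster_id = clusters$id, gene_body = gb, promoter_2kb = pr,
             repeat_el = rp, label = label, stringsAsFactors = FALSE)
}

#' Compare two cluster sets by genomic co-localization
#'
#' A cluster of A is common when it overlaps (>= 1 bp) at least one
#' cluster of B, and symmetrically; specific otherwise. Common counts
#' are per set (the two sides may differ).
#'
#' @param set_a,set_b Cluster data.frames (chrom, start, end) or
#'   `cluster_set` objects, on the same genome.
#' @param labels Character(2) set labels for the report.
#' @return List of class `common_specific_report`: per-side common /
#'   specific counts and percentages (1 d.p.).
#' @export
co_localize <- function(set_a, set_b, labels = c("A", "B")) {
  if (inherits(set_a, "cluster_set")) set_a <- set_a$clusters
  if (inherits(set_b, "cluster_set")) set_b <- set_b$clusters
  common_a <- overlaps_any(set_a, set_b)
  common_b <- overlaps_any(set_b, set_a)
  structure(list(
    labels = labels,
    n_a = nrow(set_a), n_b = nrow(set_b),
    n_common_a = sum(common_a), n_specific_a = sum(!common_a),
    n_common_b = sum(common_b), n_specific_b = sum(!common_b),
    pct_common_a = round_half_up(pct_of(sum(common_a), max(nrow(set_a), 1L)), 1),
    pct_common_b = round_half_up(pct_of(sum(common_b), max(nrow(set_b), 1L)), 1),
    common_a = common_a, common_b = common_b
  ), class = "common_specific_report")
}

#' Replicate presence and coefficient of variation per cluster
#'
#' CV = sample standard deviation (n - 1 denominator) of per-replicate
#' read counts divided by their mean, times 100. Replicates absent from
#' a cluster count as 0. CV is NA when the mean is 0.
#'
#' @param cluster_set A `cluster_set`.
#' @param n_replicates Total number of replicates in the experiment.
#' @return data.frame cluster_id, presence_count, cv.
#' @export
replicate_stats <- function(cluster_set, n_replicates) {
  if (n_replicates < 2) stop_arg("need >= 2 replicates")
  cl <- cluster_set$clusters
  all_reps <- sort(unique(unlist(lapply(cl$reads_by_replicate, names))))
  if (length(all_reps) < n_replicates) {
    all_reps <- union(all_reps,
                      sprintf("rep%d", seq_len(n_replicates)))[seq_len(n_replicates)]
  }
  res <- lapply(cl$reads_by_replicate, function(x) {
    counts <- setNames(rep(0L, n_replicates), all_reps)
    counts[names(x)] <- as.integer(x)
    m <- mean(counts)
    data.frame(presence_count = sum(counts > 0),
               cv = if (m == 0) NA_real_ else sd(counts) / m * 100)
  })
  out <- do.call(rbind, res)
  out <- cbind(cluster_id = cl$id, out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Bin clusters by read depth
#'
#' Default boundaries (5, 10, 50, 100, 500, 1000) give seven categories:
#' <=5, 6-10, 11-50, 51-100, 101-500, 501-1000, >1000.
#'
#' @param clusters Cluster data.frame (needs `reads_total`) or
#'   `cluster_set`.
#' @param boundaries Strictly increasing integer vector of upper bin
#'   edges (inclusive).
#' @return Named integer vector of bin counts (sums to the cluster
#'   count).
#' @export
depth_categories <- function(clusters,
                             boundaries = c(5L, 10L, 50L, 100L, 500L, 1000L)) {
  if (inherits(clusters, "cluster_set")) clusters <- clusters$clusters
  if (is.unsorted(boundaries, strictly = TRUE)) {
    stop_arg("boundaries must be strictly increasing")
  }
  lab <- c(paste0("<=", boundaries[1]),
           paste0(head2(boundaries) + 1, "-", boundaries[-1]),
           paste0(">", boundaries[length(boundaries)]))
  bins <- cut(clusters$reads_total, c(-Inf, boundaries, Inf), labels = lab)
  setNames(as.integer(table(bins)), lab)
}

head2 <- function(x) x[-length(x)]

#' Fisher-exact over-representation test per term
#'
#' One-sided (over-representation) Fisher exact p-value per term from
#' the 2x2 table of foreground/background vs in-term/not-in-term. No
#' multiple-testing correction is applied; a term is significant when
#' p < alpha.
#'
#' @param foreground,background Character vectors of gene ids; foreground
#'   must be non-empty and a subset of background.
#' @param term_map data.frame with columns `term_id`, `gene_id` (optional
#'   `term_name`).
#' @param alpha Significance level.
#' @return data.frame term_id, term_name, count_fg, count_bg, p_value,
#'   significant, ordered by p.
#' @export
enrichment_test <- function(foreground, background, term_map, alpha = 0.05) {
  foreground <- unique(foreground)
  background <- unique(background)
  if (length(foreground) == 0) stop_arg("foreground must be non-empty")
  if (!all(foreground %in% background)) {
    stop_arg("foreground must be a subset of background")
  }
  term_map <- term_map[term_map$gene_id %in% background, , drop = FALSE]
  terms <- unique(term_map$term_id)
  n_fg <- length(foreground); n_bg <- length(background)
  rows <- lapply(terms, function(t) {
    tg <- unique(term_map$gene_id[term_map$term_id == t])
    a <- sum(foreground %in% tg)           # fg, in term
    b <- n_fg - a                          # fg, not in term
    cc <- length(tg) - a                   # bg-only, in term
    d <- n_bg - n_fg - cc                  # bg-only, not in term
    p <- fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE),
                     alternative = "greater")$p.value
    nm <- if ("term_name" %in% names(term_map)) {
      term_map$term_name[term_map$term_id == t][1]
    } else NA_character_
    data.frame(term_id = t, term_name = nm, count_fg = a,
               count_bg = length(tg), p_value = p,
               significant = p < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$term_id), ]
  rownames(out) <- NULL
  out
}
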