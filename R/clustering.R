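# Small RNA cluster calling from read placements: coverage islands at a
# minimum raw-read depth, pad-merging of nearby islands, dicer-call
# scoring (fraction of 20-24 nt reads), size-class assignment by
# predominant read length, quantification per replicate, and matching of
# cluster reads against a known-hairpin database.

#' Cluster-calling parameters
#'
#' @param mincov Minimum per-base raw read depth that seeds an island.
#' @param pad Maximum gap (nt) between islands merged into one cluster;
#'   the boundary is inclusive (gap == pad merges).
#' @param dicer_min,dicer_max Read-length range (nt) counted as
#'   dicer-derived.
#' @param dicer_call_fraction Minimum fraction of in-range reads for a
#'   positive dicer call (boundary inclusive).
#' @return List of class `cluster_params`.
#' @export
cluster_params <- function(mincov = 5L, pad = 100L, dicer_min = 20L,
                           dicer_max = 24L, dicer_call_fraction = 0.8) {
  if (mincov < 1) stop_arg("mincov must be >= 1")
  if (pad < 0) stop_arg("pad must be >= 0")
  if (dicer_min > dicer_max) stop_arg("dicer_min must be <= dicer_max")
  structure(list(mincov = as.integer(mincov), pad = as.integer(pad),
                 dicer_min = as.integer(dicer_min),
                 dicer_max = as.integer(dicer_max),
                 dicer_call_fraction = dicer_call_fraction),
            class = "cluster_params")
}

#' Find coverage islands on one chromosome
#'
#' Maximal intervals where the per-base raw read depth is >= `mincov`.
#'
#' @param placements Placement table (single-location rows).
#' @param chromosome Chromosome name.
#' @param mincov Minimum depth.
#' @return data.frame chrom, start, end (0-based half-open).
#' @export
find_islands <- function(placements, chromosome, mincov = 5L) {
  p <- placements[placements$chrom == chromosome, , drop = FALSE]
  if (nrow(p) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  cov <- IRanges::coverage(IRanges::IRanges(p$start + 1L, p$end))
  sl <- IRanges::slice(cov, lower = mincov, rangesOnly = TRUE)
  data.frame(chrom = rep(chromosome, length(sl)),
             start = IRanges::start(sl) - 1L,
             end = IRanges::end(sl), stringsAsFactors = FALSE)
}

#' Merge islands separated by at most `pad` nucleotides
#'
#' Merging is transitive; the gap boundary is inclusive (gap == pad
#' merges, gap == pad + 1 does not).
#'
#' @param islands data.frame chrom (single value), start, end, sorted and
#'   non-overlapping.
#' @param pad Maximum merged gap (nt).
#' @return data.frame chrom, start, end.
#' @export
merge_islands <- function(islands, pad = 100L) {
  n <- nrow(islands)
  if (n <= 1) return(islands)
  o <- order(islands$start)
  s <- islands$start[o]; e <- islands$end[o]
  ms <- s[1]; me <- e[1]
  out_s <- integer(); out_e <- integer()
  for (i in seq(2, n)) {
    if (s[i] - me <= pad) {
      me <- max(me, e[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- s[i]; me <- e[i]
    }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)
  data.frame(chrom = islands$chrom[1], start = out_s, end = out_e,
             stringsAsFactors = FALSE)
}

#' Build small RNA clusters from placements
#'
#' One cluster per merged island interval; every placement overlapping
#' the merged interval is assigned to it and the cluster extent is
#' extended to the min start / max end of its assigned reads. Read-length
#' and per-replicate histograms are tallied; rpm is reads_total over the
#' total mapped reads in the sample times 1e6.
#'
#' @param placements Placement table from [map_readset()] (single
#'   location per read).
#' @param params A `cluster_params`.
#' @param total_mapped_reads rpm denominator; defaults to
#'   `nrow(placements)`.
#' @return List of class `cluster_set`: `clusters` (data.frame with
#'   list-columns reads_by_length, reads_by_replicate), `assignments`
#'   (read_id -> cluster_id), `params`, `total_mapped_reads`.
#' @export
build_clusters <- function(placements, params = cluster_params(),
                           total_mapped_reads = NULL) {
  if (is.null(total_mapped_reads)) total_mapped_reads <- nrow(placements)
  empty <- data.frame(id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      reads_total = integer(), rpm = numeric(),
                      dicer_call = logical(), size_class = integer(),
                      mirna_match = character(), stringsAsFactors = FALSE)
  if (nrow(placements) == 0) {
    empty$reads_by_length <- list()
    empty$reads_by_replicate <- list()
    return(structure(list(clusters = empty,
                          assignments = data.frame(read_id = character(),
                                                   cluster_id = character()),
                          params = params,
                          total_mapped_reads = total_mapped_reads),
                     class = "cluster_set"))
  }
  rows <- list(); asg <- list()
  for (ch in sort(unique(placements$chrom))) {
    p <- placements[placements$chrom == ch, , drop = FALSE]
    isl <- find_islands(p, ch, params$mincov)
    if (nrow(isl) == 0) next
    merged <- merge_islands(isl, params$pad)
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(p$start + 1L, p$end),
      IRanges::IRanges(merged$start + 1L, merged$end),
      select = "first")
    for (j in seq_len(nrow(merged))) {
      sel <- which(ov == j)
      if (!length(sel)) next
      q <- p[sel, , drop = FALSE]
      lens <- q$end - q$start
      by_len <- table(lens)
      by_rep <- table(q$replicate, useNA = "no")
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = min(q$start), end = max(q$end),
        reads_total = nrow(q),
        stringsAsFactors = FALSE)
      attr(rows[[length(rows)]], "by_len") <-
        setNames(as.integer(by_len), names(by_len))
      attr(rows[[length(rows)]], "by_rep") <-
        setNames(as.integer(by_rep), names(by_rep))
      asg[[length(asg) + 1L]] <- q$read_id
    }
  }
  if (!length(rows)) {
    empty$reads_by_length <- list()
    empty$reads_by_replicate <- list()
    return(structure(list(clusters = empty,
                          assignments = data.frame(read_id = character(),
                                                   cluster_id = character()),
                          params = params,
                          total_mapped_reads = total_mapped_reads),
                     class = "cluster_set"))
  }
  cl <- do.call(rbind, rows)
  cl <- cbind(id = sprintf("cl_%05d", seq_len(nrow(cl))), cl,
              stringsAsFactors = FALSE)
  cl$rpm <- cl$reads_total / total_mapped_reads * 1e6
  cl$dicer_call <- NA
  cl$size_class <- NA_integer_
  cl$mirna_match <- NA_character_
  cl$reads_by_length <- lapply(rows, attr, "by_len")
  cl$reads_by_replicate <- lapply(rows, attr, "by_rep")
  rownames(cl) <- NULL
  assignments <- data.frame(
    read_id = unlist(asg),
    cluster_id = rep(cl$id, vapply(asg, length, integer(1))),
    stringsAsFactors = FALSE)
  structure(list(clusters = cl, assignments = assignments, params = params,
                 total_mapped_reads = total_mapped_reads),
            class = "cluster_set")
}

#' Score the dicer call and size class of each cluster
#'
#' A cluster is dicer-derived when the fraction of its reads with length
#' in [dicer_min, dicer_max] is >= `dicer_call_fraction` (inclusive,
#' computed in integer arithmetic so the 80% boundary is exact). The size
#' class of a dicer-derived cluster is its modal read length restricted
#' to the dicer range; ties go to the larger length.
#'
#' @param cluster_set A `cluster_set` from [build_clusters()].
#' @param params A `cluster_params` (defaults to the set's own).
#' @return The `cluster_set` with `dicer_call` and `size_class` filled.
#' @export
call_dicer <- function(cluster_set, params = NULL) {
  if (is.null(params)) params <- cluster_set$params
  cl <- cluster_set$clusters
  frac_num <- round(params$dicer_call_fraction * 10000)
  for (i in seq_len(nrow(cl))) {
    by_len <- cl$reads_by_length[[i]]
    lens <- as.integer(names(by_len))
    total <- sum(by_len)
    in_range <- lens >= params$dicer_min & lens <= params$dicer_max
    n_in <- sum(by_len[in_range])
    # n_in / total >= fraction, exactly, in integers
    cl$dicer_call[i] <- (n_in * 10000 >= total * frac_num)
    if (cl$dicer_call[i]) {
      cand <- by_len[in_range]
      cand_len <- lens[in_range]
      best <- max(cand)
      cl$size_class[i] <- max(cand_len[cand == best])
    } else {
      cl$size_class[i] <- NA_integer_
    }
  }
  cluster_set$clusters <- cl
  cluster_set
}

# Sliding-window Hamming match of a query against one subject; returns
# the minimum mismatch count over all ungapped windows (Inf if the query
# is longer than the subject).
min_hamming_window <- function(query, subject) {
  m <- nchar(query); H <- nchar(subject)
  if (m > H) return(Inf)
  q <- strsplit(query, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  best <- Inf
  for (i in seq_len(H - m + 1L)) {
    d <- sum(q != s[i:(i + m - 1L)])
    if (d < best) best <- d
    if (best == 0) break
  }
  best
}

#' Match clusters against a known-miRNA hairpin database
#'
#' For each cluster, the most abundant read sequence (ties broken
#' lexicographically) is matched as an ungapped substring of each hairpin
#' with at most `max_mismatches` mismatches. The best hit is the hairpin
#' with the fewest mismatches; ties are broken by database order.
#'
#' @param cluster_set A `cluster_set`.
#' @param reads Read data.frame the clusters were built from (provides
#'   sequences per read id).
#' @param hairpin_db Named character vector of hairpin sequences.
#' @param max_mismatches Maximum Hamming distance for a match.
#' @return The `cluster_set` with `mirna_match` filled (NA = no match).
#' @export
match_known_mirna <- function(cluster_set, reads, hairpin_db,
                              max_mismatches = 2L) {
  if (is.null(hairpin_db) || length(hairpin_db) == 0) {
    stop_arg("hairpin_db must be non-empty")
  }
  reads <- as_read_df(reads)
  seq_of <- setNames(reads$sequence, reads$id)
  cl <- cluster_set$clusters
  asg <- split(cluster_set$assignments$read_id,
               cluster_set$assignments$cluster_id)
  for (i in seq_len(nrow(cl))) {
    ids <- asg[[cl$id[i]]]
    if (is.null(ids)) next
    sq <- seq_of[ids]
    tab <- sort(table(sq), decreasing = TRUE)
    top <- names(tab)[tab == tab[1]]
    query <- sort(top)[1]
    best_mm <- Inf; best_hp <- NA_character_
    for (j in seq_along(hairpin_db)) {
      mm <- min_hamming_window(query, hairpin_db[[j]])
      if (mm < best_mm) {
        best_mm <- mm; best_hp <- names(hairpin_db)[j]
      }
    }
    cl$mirna_match[i] <- if (best_mm <= max_mismatches) best_hp else NA_character_
  }
  cluster_set$clusters <- cl
  cluster_set
}

#' Export a cluster set as a results TSV + BED6
#'
#' @param cluster_set A `cluster_set`.
#' @param tsv_path,bed_path Output paths (NULL skips either).
#' @return The flattened results data.frame, invisibly.
#' @export
export_clusters <- function(cluster_set, tsv_path = NULL, bed_path = NULL) {
  cl <- cluster_set$clusters
  lens <- sort(unique(unlist(lapply(cl$reads_by_length, names))))
  reps <- sort(unique(unlist(lapply(cl$reads_by_replicate, names))))
  flat <- cl[, c("id", "chrom", "start", "end", "reads_total", "rpm",
                 "dicer_call", "size_class", "mirna_match")]
  for (l in lens) {
    flat[[paste0("len_", l)]] <- vapply(cl$reads_by_length, function(x) {
      v <- x[l]; if (is.na(v)) 0L else as.integer(v)
    }, integer(1))
  }
  for (r in reps) {
    flat[[paste0("n_", r)]] <- vapply(cl$reads_by_replicate, function(x) {
      v <- x[r]; if (is.na(v)) 0L else as.integer(v)
    }, integer(1))
  }
  if (!is.null(tsv_path)) write_tsv(flat, tsv_path)
  if (!is.null(bed_path)) {
    write_bed(data.frame(chrom = cl$chrom, start = cl$start, end = cl$end,
                         id = cl$id, score = cl$reads_total,
                         strand = "."), bed_path)
  }
  invisible(flat)
}
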