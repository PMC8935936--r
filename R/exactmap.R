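# Exact-occurrence placement of short reads on a genome, both strands.
#
# Mapping is exact-match only (0 mismatches) throughout the pipeline: the
# SNP-discriminative mobility classification is defined in terms of 100%
# homology, and uniform exactness keeps the downstream logic
# self-consistent. Placements use the package-wide 0-based half-open
# convention; a "-" strand placement means the reverse complement of the
# genome substring equals the read.

#' Build an exact-match index over a genome
#'
#' @param genome Named character vector of chromosome sequences (ACGTN).
#' @param seed_length Minimum query length supported (nt).
#' @return An `exact_index` object.
#' @export
build_index <- function(genome, seed_length = 17L) {
  if (length(genome) == 0 || all(nchar(genome) == 0)) {
    stop_arg("genome must be non-empty")
  }
  if (is.null(names(genome))) stop_arg("genome chromosomes must be named")
  check_genome_chars(genome)
  structure(list(
    seqs = Biostrings::DNAStringSet(genome),
    chrom_lengths = setNames(nchar(genome), names(genome)),
    seed_length = as.integer(seed_length)
  ), class = "exact_index")
}

#' Mapping parameters
#'
#' @param multimap_policy How reads with several exact genomic occurrences
#'   are resolved: `"random_one"` keeps one occurrence chosen uniformly
#'   with the seeded generator, `"all"` keeps every occurrence,
#'   `"unique_only"` drops multimapping reads.
#' @param rng_seed Seed for the `random_one` draw (reproducible
#'   bit-exactly).
#' @return List of class `map_params`.
#' @export
map_params <- function(multimap_policy = c("random_one", "all", "unique_only"),
                       rng_seed = 1L) {
  structure(list(multimap_policy = match.arg(multimap_policy),
                 rng_seed = as.integer(rng_seed)),
            class = "map_params")
}

# All exact occurrences of one sequence, both strands (matchPattern based;
# used by place_read and as the per-read path of map_readset).
occurrences_of <- function(index, seq) {
  hits <- list()
  rc <- revcomp(seq)
  for (ch in names(index$chrom_lengths)) {
    subj <- index$seqs[[ch]]
    for (str in c("+", "-")) {
      pat <- if (str == "+") seq else rc
      m <- Biostrings::matchPattern(pat, subj, fixed = TRUE)
      if (length(m)) {
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = ch, start = Biostrings::start(m) - 1L,
          end = Biostrings::end(m), strand = str,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), stringsAsFactors = FALSE)
}

#' Place one read on the genome
#'
#' Returns all exact occurrences on both strands, subject to the
#' multimapping policy. `n_occurrences` always records the total number
#' of exact hits genome-wide.
#'
#' @param index An `exact_index`.
#' @param read Read sequence (character scalar).
#' @param params A `map_params`.
#' @return data.frame with columns chrom, start, end, strand,
#'   n_occurrences (possibly zero rows).
#' @export
place_read <- function(index, read, params = map_params()) {
  if (nchar(read) < index$seed_length) {
    stop_arg("read shorter than index seed_length")
  }
  occ <- occurrences_of(index, read)
  n <- nrow(occ)
  if (n == 0) {
    occ$n_occurrences <- integer(0)
    return(occ)
  }
  occ$n_occurrences <- n
  switch(params$multimap_policy,
         all = occ,
         unique_only = if (n > 1) occ[0, ] else occ,
         random_one = {
           set.seed(params$rng_seed)
           occ[sample(n, 1), , drop = FALSE]
         })
}

# Occurrence table for a set of unique sequences of equal width against
# all chromosomes / strands, via a constant-width PDict. Sequences with
# non-ACGT characters get zero occurrences.
occ_table_width <- function(index, seqs) {
  ok <- !grepl("[^ACGT]", seqs)
  out <- list()
  if (any(ok)) {
    dss <- Biostrings::DNAStringSet(seqs[ok])
    idx_ok <- which(ok)
    pd_f <- Biostrings::PDict(dss)
    pd_r <- Biostrings::PDict(Biostrings::reverseComplement(dss))
    for (ch in names(index$chrom_lengths)) {
      subj <- index$seqs[[ch]]
      for (str in c("+", "-")) {
        pd <- if (str == "+") pd_f else pd_r
        m <- Biostrings::matchPDict(pd, subj)
        st <- Biostrings::startIndex(m)
        cnt <- lengths(st)
        if (sum(cnt) == 0) next
        out[[length(out) + 1L]] <- data.frame(
          seq_idx = rep(idx_ok, cnt),
          chrom = ch,
          start = unlist(st) - 1L,
          strand = str,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(seq_idx = integer(), chrom = character(), start = integer(),
               strand = character(), stringsAsFactors = FALSE)
}

#' Map a read set to a genome
#'
#' Exact placement of every read, with deterministic multimapper
#' resolution. The mapped/unmapped partition depends only on whether a
#' read has >= 1 exact occurrence (plus the `unique_only` policy).
#'
#' @param index An `exact_index`.
#' @param reads Read data.frame (id, sequence, replicate) or named
#'   character vector.
#' @param params A `map_params`.
#' @return List: `placements` (read_id, chrom, start, end, strand,
#'   n_occurrences, replicate), `mapped_ids`, `unmapped_ids`,
#'   `mapped_fraction`.
#' @export
map_readset <- function(index, reads, params = map_params()) {
  reads <- as_read_df(reads)
  n <- nrow(reads)
  if (n == 0) {
    return(list(placements = data.frame(), mapped_ids = character(),
                unmapped_ids = character(), mapped_fraction = NA_real_))
  }
  useq <- unique(reads$sequence)
  widths <- nchar(useq)
  occ_parts <- list()
  for (w in unique(widths)) {
    sel <- which(widths == w)
    occ <- occ_table_width(index, useq[sel])
    if (nrow(occ)) {
      occ$useq_idx <- sel[occ$seq_idx]
      occ_parts[[length(occ_parts) + 1L]] <-
        occ[, c("useq_idx", "chrom", "start", "strand")]
    }
  }
  occ_all <- if (length(occ_parts)) do.call(rbind, occ_parts) else
    data.frame(useq_idx = integer(), chrom = character(),
               start = integer(), strand = character(),
               stringsAsFactors = FALSE)
  occ_all <- occ_all[order(occ_all$useq_idx, occ_all$chrom,
                           occ_all$start, occ_all$strand), ]
  n_occ_useq <- tabulate(occ_all$useq_idx, nbins = length(useq))
  # row offset of each unique sequence's first occurrence in occ_all
  offset <- c(0L, cumsum(n_occ_useq))[seq_along(useq)]

  ridx <- match(reads$sequence, useq)
  read_nocc <- n_occ_useq[ridx]
  mapped <- read_nocc > 0
  if (params$multimap_policy == "unique_only") mapped <- read_nocc == 1

  set.seed(params$rng_seed)
  pick <- rep(1L, n)
  multi <- mapped & read_nocc > 1
  if (params$multimap_policy == "random_one" && any(multi)) {
    pick[multi] <- floor(runif(sum(multi)) * read_nocc[multi]) + 1L
  }

  plc <- NULL
  mi <- which(mapped)
  if (length(mi)) {
    if (params$multimap_policy == "all") {
      reps <- read_nocc[mi]
      rows <- unlist(lapply(mi, function(j) offset[ridx[j]] + seq_len(read_nocc[j])))
      occ <- occ_all[rows, c("chrom", "start", "strand")]
      plc <- data.frame(read_id = rep(reads$id[mi], reps),
                        occ,
                        n_occurrences = rep(read_nocc[mi], reps),
                        replicate = rep(reads$replicate[mi], reps),
                        width = rep(nchar(reads$sequence[mi]), reps),
                        stringsAsFactors = FALSE)
    } else {
      rows <- offset[ridx[mi]] + pick[mi]
      occ <- occ_all[rows, c("chrom", "start", "strand")]
      plc <- data.frame(read_id = reads$id[mi], occ,
                        n_occurrences = read_nocc[mi],
                        replicate = reads$replicate[mi],
                        width = nchar(reads$sequence[mi]),
                        stringsAsFactors = FALSE)
    }
    plc$end <- plc$start + plc$width
    plc$width <- NULL
    plc <- plc[, c("read_id", "chrom", "start", "end", "strand",
                   "n_occurrences", "replicate")]
    rownames(plc) <- NULL
  } else {
    plc <- data.frame(read_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), n_occurrences = integer(),
                      replicate = character(), stringsAsFactors = FALSE)
  }
  list(placements = plc,
       mapped_ids = reads$id[mapped],
       unmapped_ids = reads$id[!mapped],
       mapped_fraction = mean(mapped))
}

#' Export placements as BED6 (score = n_occurrences)
#'
#' @param placements Placement table from [map_readset()].
#' @param path Output path.
#' @export
placements_to_bed <- function(placements, path) {
  write_bed(data.frame(chrom = placements$chrom, start = placements$start,
                       end = placements$end, id = placements$read_id,
                       score = placements$n_occurrences,
                       strand = placements$strand), path)
}
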