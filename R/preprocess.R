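# Read cleaning: adapter trimming, minimum-length filtering,
# low-complexity removal, exact-match decontamination. The stage order is
# fixed (trim -> length -> complexity -> contaminants) and the read count
# is monotonically non-increasing across stages.

#' Trim the 3' adapter from reads
#'
#' The earliest occurrence of an adapter prefix of length >=
#' `min_overlap` anchored at the read's 3' end — or of the full adapter
#' internally — is removed together with everything 3' of it. Reads
#' without a qualifying match are returned unchanged.
#'
#' @param reads Read data.frame or character vector of sequences.
#' @param adapter Adapter sequence.
#' @param min_overlap Minimum adapter prefix length that triggers a trim.
#' @return Same shape as `reads`, sequences trimmed.
#' @export
trim_adapter <- function(reads, adapter = DEFAULT_ADAPTER, min_overlap = 3L) {
  if (min_overlap < 1 || min_overlap > nchar(adapter)) {
    stop_arg("need adapter length >= min_overlap >= 1")
  }
  vec_in <- !is.data.frame(reads)
  df <- as_read_df(reads)
  seqs <- df$sequence
  len <- nchar(seqs)
  alen <- nchar(adapter)
  # earliest full internal adapter occurrence (1-based position, -1 if none)
  ipos <- regexpr(adapter, seqs, fixed = TRUE)
  cut <- ifelse(ipos > 0, ipos, len + 1L)
  # suffix-of-read == prefix-of-adapter overlaps, longest (= earliest) first
  hi <- min(alen - 1L, if (length(len)) max(len) else 0L)
  if (hi >= min_overlap) {
    for (k in hi:min_overlap) {
      pref <- substr(adapter, 1L, k)
      hit <- len >= k & substr(seqs, len - k + 1L, len) == pref
      cand <- len - k + 1L
      cut <- ifelse(hit & cand < cut, cand, cut)
    }
  }
  df$sequence <- substr(seqs, 1L, cut - 1L)
  if (vec_in) setNames(df$sequence, df$id) else df
}

#' Keep reads of at least a minimum length
#'
#' @param reads Read data.frame or character vector.
#' @param min_len Minimum retained length (nt); the boundary is
#'   inclusive (a `min_len`-nt read is kept).
#' @export
filter_length <- function(reads, min_len = 17L) {
  if (min_len < 1) stop_arg("min_len must be >= 1")
  vec_in <- !is.data.frame(reads)
  df <- as_read_df(reads)
  keep <- nchar(df$sequence) >= min_len
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  if (vec_in) setNames(df$sequence, df$id) else df
}

#' Mononucleotide Shannon entropy of each read (bits)
#'
#' @param seqs Character vector of sequences.
#' @return Numeric vector in [0, 2].
#' @export
sequence_entropy <- function(seqs) {
  dss <- Biostrings::DNAStringSet(seqs)
  f <- Biostrings::letterFrequency(dss, c("A", "C", "G", "T"))
  p <- f / pmax(rowSums(f), 1L)
  plogp <- ifelse(p > 0, p * log2(p), 0)
  -rowSums(plogp)
}

#' Remove low-complexity reads
#'
#' Drops reads whose base-composition Shannon entropy is below
#' `entropy_threshold` (keeps entropy >= threshold).
#'
#' @param reads Read data.frame or character vector.
#' @param entropy_threshold Threshold in bits, in [0, 2].
#' @export
filter_low_complexity <- function(reads, entropy_threshold = 0.5) {
  if (entropy_threshold < 0 || entropy_threshold > 2) {
    stop_arg("entropy threshold must be in [0, 2] bits")
  }
  vec_in <- !is.data.frame(reads)
  df <- as_read_df(reads)
  if (nrow(df)) {
    keep <- sequence_entropy(df$sequence) >= entropy_threshold
    df <- df[keep, , drop = FALSE]
    rownames(df) <- NULL
  }
  if (vec_in) setNames(df$sequence, df$id) else df
}

#' Remove reads matching contaminant references exactly
#'
#' A read is removed when its sequence — or its reverse complement —
#' occurs exactly (no mismatch) within any contaminant reference.
#'
#' @param reads Read data.frame or character vector.
#' @param contaminant_refs Named character vector of reference sequences
#'   (rRNA/tRNA, chloroplast genome, ...).
#' @return List: `kept` (same shape as input), `removed_count`.
#' @export
filter_contaminants <- function(reads, contaminant_refs) {
  if (is.null(contaminant_refs) || length(contaminant_refs) == 0) {
    stop_arg("contaminant references must be non-empty")
  }
  vec_in <- !is.data.frame(reads)
  df <- as_read_df(reads)
  if (nrow(df) == 0) {
    return(list(kept = if (vec_in) character() else df, removed_count = 0L))
  }
  idx <- build_index(contaminant_refs,
                     seed_length = min(nchar(df$sequence)))
  # occurrence anywhere (either strand) decides removal
  useq <- unique(df$sequence)
  hit_useq <- logical(length(useq))
  for (w in unique(nchar(useq))) {
    sel <- which(nchar(useq) == w)
    occ <- occ_table_width(idx, useq[sel])
    hit_useq[sel[unique(occ$seq_idx)]] <- TRUE
  }
  removed <- hit_useq[match(df$sequence, useq)]
  kept <- df[!removed, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = if (vec_in) setNames(kept$sequence, kept$id) else kept,
       removed_count = sum(removed))
}

#' Run the full preprocessing pipeline on one library
#'
#' Fixed stage order: adapter trim, minimum length, low complexity,
#' contaminant removal.
#'
#' @param reads Read data.frame.
#' @param adapter Adapter sequence.
#' @param min_len Minimum read length retained.
#' @param entropy_threshold Complexity threshold (bits).
#' @param contaminant_refs Named character vector, or NULL to skip
#'   decontamination.
#' @param min_overlap Adapter trimming minimum overlap.
#' @return List: `reads` (cleaned), `stage_counts` (data.frame stage,
#'   reads_out).
#' @export
preprocess_reads <- function(reads, adapter = DEFAULT_ADAPTER,
                             min_len = 17L, entropy_threshold = 0.5,
                             contaminant_refs = NULL, min_overlap = 3L) {
  reads <- as_read_df(reads)
  counts <- data.frame(stage = "input", reads_out = nrow(reads))
  reads <- trim_adapter(reads, adapter, min_overlap)
  counts <- rbind(counts, data.frame(stage = "adapter_trim",
                                     reads_out = nrow(reads)))
  reads <- filter_length(reads, min_len)
  counts <- rbind(counts, data.frame(stage = "length_filter",
                                     reads_out = nrow(reads)))
  reads <- filter_low_complexity(reads, entropy_threshold)
  counts <- rbind(counts, data.frame(stage = "complexity_filter",
                                     reads_out = nrow(reads)))
  if (!is.null(contaminant_refs)) {
    fc <- filter_contaminants(reads, contaminant_refs)
    reads <- fc$kept
  }
  counts <- rbind(counts, data.frame(stage = "decontamination",
                                     reads_out = nrow(reads)))
  list(reads = reads, stage_counts = counts)
}
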