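#' @keywords internal
"_PACKAGE"

#' @importFrom stats runif rbinom fisher.test sd setNames
#' @importFrom utils read.delim write.table
NULL

# Round half away from zero (the convention used throughout the report
# tables; base round() rounds half to even).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Percentage of a count over a denominator, NA-safe (0 with a flag handled
# by callers when denom == 0).
pct_of <- function(num, denom) {
  if (denom == 0) return(0)
  num / denom * 100
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Coerce a character vector of sequences to the canonical read data.frame
# (columns id, sequence, replicate).
as_read_df <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("id", "sequence") %in% names(x)))
    if (is.null(x$replicate)) x$replicate <- NA_character_
    return(x)
  }
  ids <- names(x)
  if (is.null(ids)) ids <- sprintf("read_%06d", seq_along(x))
  data.frame(id = ids, sequence = unname(as.character(x)),
             replicate = rep(NA_character_, length(x)),
             stringsAsFactors = FALSE)
}

# Deterministic child seed derivation, kept below 2^31.
derive_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(k) * 7919L %% 2147483L
}

stop_arg <- function(...) stop(..., call. = FALSE)

check_genome_chars <- function(genome) {
  bad <- grepl("[^ACGTN]", genome)
  if (any(bad)) {
    stop_arg("genome sequence(s) contain non-ACGTN characters: ",
             paste(names(genome)[bad], collapse = ", "))
  }
  invisible(TRUE)
}
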