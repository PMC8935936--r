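# Readers and writers for the standard formats the pipeline touches.
#
# Coordinate convention: everything inside the package is 0-based,
# half-open [start, end). Only the GFF3 (1-based inclusive) and BED
# (0-based half-open) boundary layers convert.

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased on input. Duplicate record names, empty
#' sequences and non-IUPAC characters are format errors.
#'
#' @param path Path to a FASTA file (plain or gzip).
#' @return Named character vector, one element per record.
#' @export
read_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(dss))
  if (anyDuplicated(nm)) stop_arg("duplicate FASTA record names in ", path)
  if (any(Biostrings::width(dss) == 0)) {
    stop_arg("empty sequence record in ", path)
  }
  setNames(toupper(as.character(dss)), nm)
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    stop_arg("all sequences must be named")
  }
  if (any(nchar(seqs) == 0)) stop_arg("refusing to write empty sequence")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTQ file into a read table
#'
#' Gzip-compressed input is handled transparently. Sequence/quality length
#' mismatches and truncated records are format errors.
#'
#' @param path Path to a FASTQ file.
#' @param replicate Optional replicate label attached to every read.
#' @return data.frame with columns `id`, `sequence`, `replicate`.
#' @export
read_fastq <- function(path, replicate = NA_character_) {
  con <- gzfile(path, "rt")   # transparently reads plain files too
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) %% 4 != 0) {
    stop_arg("malformed FASTQ ", path, ": truncated record")
  }
  n <- length(lines) %/% 4
  hdr <- lines[seq(1, length(lines), by = 4)]
  seqs <- lines[seq(2, length(lines), by = 4)]
  plus <- lines[seq(3, length(lines), by = 4)]
  qual <- lines[seq(4, length(lines), by = 4)]
  if (n > 0 && (!all(startsWith(hdr, "@")) || !all(startsWith(plus, "+")))) {
    stop_arg("malformed FASTQ ", path, ": bad record delimiter")
  }
  if (any(nchar(seqs) != nchar(qual))) {
    stop_arg("malformed FASTQ ", path, ": sequence/quality length mismatch")
  }
  data.frame(id = sub("\\s.*$", "", substring(hdr, 2)),
             sequence = toupper(seqs),
             replicate = rep(replicate, n),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a read table as FASTQ (Phred+33, constant quality "I")
#'
#' @param reads data.frame with `id` and `sequence` columns, or a named
#'   character vector.
#' @param path Output path; `.gz` suffix triggers compression.
#' @export
write_fastq <- function(reads, path) {
  reads <- as_read_df(reads)
  dss <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$id))
  qual <- Biostrings::PhredQuality(strrep("I", nchar(reads$sequence)))
  qdss <- Biostrings::QualityScaledDNAStringSet(dss, qual)
  Biostrings::writeQualityScaledXStringSet(qdss, path,
                                           compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a GFF3 file into a feature annotation
#'
#' GFF3 is 1-based inclusive; intervals are converted to the internal
#' 0-based half-open convention. Features of type "gene" populate the gene
#' set; types containing "repeat" or "transposable" populate the repeat
#' set. Comment and directive lines are skipped by the parser.
#'
#' @param path Path to a GFF3 file.
#' @return A `feature_annotation`: list with data.frames `genes` and
#'   `repeats` (columns chrom, start, end, strand, id).
#' @export
read_gff3 <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop_arg("malformed GFF3 ", path, ": ",
                                              conditionMessage(e)))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    id = if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_,
    stringsAsFactors = FALSE
  )
  df$strand[df$strand == "*"] <- "."
  missing_id <- is.na(df$id)
  df$id[missing_id] <- sprintf("feat_%05d", which(missing_id))
  genes <- df[df$type == "gene", c("chrom", "start", "end", "strand", "id")]
  reps <- df[grepl("repeat|transposable", df$type, ignore.case = TRUE),
             c("chrom", "start", "end", "strand", "id")]
  rownames(genes) <- rownames(reps) <- NULL
  feature_annotation(genes = genes, repeats = reps)
}

#' Write a feature annotation as GFF3
#'
#' @param annotation A `feature_annotation`.
#' @param path Output path.
#' @export
write_gff3 <- function(annotation, path) {
  blocks <- list(gene = annotation$genes, repeat_region = annotation$repeats)
  grs <- lapply(names(blocks), function(ty) {
    b <- blocks[[ty]]
    if (is.null(b) || nrow(b) == 0) return(NULL)
    gr <- GenomicRanges::GRanges(
      b$chrom,
      IRanges::IRanges(b$start + 1L, b$end),
      strand = ifelse(b$strand %in% c("+", "-"), b$strand, "*")
    )
    gr$type <- ty
    gr$ID <- b$id
    gr
  })
  grs <- grs[!vapply(grs, is.null, logical(1))]
  gr <- if (length(grs)) do.call(c, grs) else
    GenomicRanges::GRanges()
  gr$source <- "graftmobile"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Construct a feature annotation container
#'
#' @param genes,repeats data.frames with columns chrom, start, end,
#'   strand, id (0-based half-open intervals).
#' @return List of class `feature_annotation`.
#' @export
feature_annotation <- function(genes = NULL, repeats = NULL) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      id = character(), stringsAsFactors = FALSE)
  if (is.null(genes)) genes <- empty
  if (is.null(repeats)) repeats <- empty
  for (b in list(genes, repeats)) {
    if (nrow(b) && any(b$start >= b$end)) {
      stop_arg("feature interval with start >= end")
    }
  }
  structure(list(genes = genes, repeats = repeats),
            class = "feature_annotation")
}

#' Export intervals as BED6
#'
#' Intervals are already 0-based half-open internally, so coordinates are
#' written verbatim (BED standard).
#'
#' @param df data.frame with chrom, start, end plus optional id/score/strand.
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  out <- data.frame(
    chrom = df$chrom,
    start = df$start,
    end = df$end,
    name = if (!is.null(df$id)) df$id else ".",
    score = if (!is.null(df$score)) df$score else 0L,
    strand = if (!is.null(df$strand)) df$strand else "."
  )
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read a plain TSV with header
#' @param df data.frame. @param path file path.
#' @export
write_tsv <- function(df, path) {
  flat <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
  write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
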