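# Synthetic heterograft data with known ground truth.
#
# The generator emulates a heterograft sequencing experiment: two genomes
# (scion donor vs rootstock receptor) identical except at SNP positions,
# small RNA loci of defined size classes, and per-compartment read
# populations carrying a configurable mobile fraction, replicate
# structure, sequencing error and contaminant admixture. Every read's
# provenance (source genome, locus, SNP-spanning status, error count) is
# recorded so downstream classification can be scored against truth.

DEFAULT_ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"

#' Simulate a SNP-diverged genome pair
#'
#' The two genomes have identical chromosome lengths and differ exactly at
#' the returned SNP positions. SNPs are placed independently per position
#' at rate `snp_rate`; the receptor allele at a SNP site is drawn
#' uniformly from the three non-donor bases.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param length Length of each chromosome (nt).
#' @param snp_rate Per-position divergence probability in [0, 1].
#' @param seed Integer seed; output is deterministic per seed.
#' @return List of class `genome_pair`: `donor`, `receptor` (named
#'   character vectors) and `snp_table` (data.frame chrom, pos (0-based),
#'   donor_allele, receptor_allele).
#' @export
simulate_genome_pair <- function(n_chromosomes = 2, length = 100000,
                                 snp_rate = 0.005, seed = 1) {
  if (length <= 0) stop_arg("chromosome length must be positive")
  if (snp_rate < 0 || snp_rate > 1) stop_arg("snp_rate must be in [0, 1]")
  if (n_chromosomes < 1) stop_arg("need at least one chromosome")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  donor <- receptor <- character(n_chromosomes)
  snp <- vector("list", n_chromosomes)
  for (i in seq_len(n_chromosomes)) {
    d <- sample(bases, length, replace = TRUE)
    is_snp <- runif(length) < snp_rate
    # the allele shift is pre-drawn for every position so the RNG stream
    # does not depend on snp_rate: for a fixed seed, SNP sets are nested
    # across rates (common random numbers)
    shift <- sample(1:3, length, replace = TRUE)
    r <- d
    if (any(is_snp)) {
      at <- which(is_snp)
      # uniform over the 3 non-donor bases: shift donor index by 1..3
      didx <- match(d[at], bases)
      r[at] <- bases[((didx - 1L + shift[at]) %% 4L) + 1L]
    }
    donor[i] <- paste(d, collapse = "")
    receptor[i] <- paste(r, collapse = "")
    snp[[i]] <- data.frame(chrom = rep(sprintf("chr%d", i), sum(is_snp)),
                           pos = which(is_snp) - 1L,
                           donor_allele = d[is_snp],
                           receptor_allele = r[is_snp],
                           stringsAsFactors = FALSE)
  }
  names(donor) <- names(receptor) <- sprintf("chr%d", seq_len(n_chromosomes))
  structure(list(donor = donor, receptor = receptor,
                 snp_table = do.call(rbind, snp)),
            class = "genome_pair")
}

#' Plant gene and repeat annotations on a genome pair
#'
#' Genes are non-overlapping stranded intervals; repeats are placed
#' uniformly and may overlap genes. Deterministic per seed.
#'
#' @param pair A `genome_pair`.
#' @param n_genes,n_repeats Feature counts across the whole genome.
#' @param gene_length,repeat_length Integer ranges (min, max) the feature
#'   lengths are drawn from.
#' @param seed Integer seed.
#' @return A `feature_annotation`.
#' @export
plant_annotations <- function(pair, n_genes, n_repeats,
                              gene_length = c(300L, 1500L),
                              repeat_length = c(200L, 1000L),
                              seed = 1) {
  set.seed(seed)
  chroms <- names(pair$donor)
  lens <- nchar(pair$donor)
  # allocate features to chromosomes proportionally to length
  alloc <- function(n) {
    if (n == 0) return(setNames(integer(length(chroms)), chroms))
    a <- floor(n * lens / sum(lens))
    rem <- n - sum(a)
    if (rem > 0) a[seq_len(rem)] <- a[seq_len(rem)] + 1L
    setNames(as.integer(a), chroms)
  }
  gene_alloc <- alloc(n_genes)
  genes <- list()
  for (ch in chroms) {
    k <- gene_alloc[[ch]]
    if (k == 0) next
    gl <- sample(seq(gene_length[1], gene_length[2]), k, replace = TRUE)
    slack <- lens[[ch]] - sum(gl)
    if (slack < k) stop_arg("cannot pack ", k, " genes into ", ch)
    gaps <- as.vector(stats::rmultinom(1, slack, rep(1, k + 1)))
    starts <- cumsum(gaps[seq_len(k)]) + c(0L, cumsum(gl))[seq_len(k)]
    genes[[ch]] <- data.frame(chrom = ch, start = as.integer(starts),
                              end = as.integer(starts + gl),
                              strand = sample(c("+", "-"), k, replace = TRUE),
                              stringsAsFactors = FALSE)
  }
  genes <- if (length(genes)) do.call(rbind, genes) else NULL
  if (!is.null(genes)) {
    genes$id <- sprintf("gene_%04d", seq_len(nrow(genes)))
    rownames(genes) <- NULL
  }
  rep_alloc <- alloc(n_repeats)
  reps <- list()
  for (ch in chroms) {
    k <- rep_alloc[[ch]]
    if (k == 0) next
    rl <- sample(seq(repeat_length[1], repeat_length[2]), k, replace = TRUE)
    if (any(rl >= lens[[ch]])) stop_arg("repeat longer than chromosome ", ch)
    starts <- floor(runif(k) * (lens[[ch]] - rl))
    reps[[ch]] <- data.frame(chrom = ch, start = as.integer(starts),
                             end = as.integer(starts + rl),
                             strand = sample(c("+", "-"), k, replace = TRUE),
                             stringsAsFactors = FALSE)
  }
  reps <- if (length(reps)) do.call(rbind, reps) else NULL
  if (!is.null(reps)) {
    reps$id <- sprintf("repeat_%04d", seq_len(nrow(reps)))
    rownames(reps) <- NULL
  }
  feature_annotation(genes = genes, repeats = reps)
}

#' Plant small RNA loci of defined size classes
#'
#' Emulates the locus classes observed in plant small RNA populations:
#' 21-nt siRNA loci inside gene bodies, 24-nt siRNA loci inside 2-kb
#' promoters or repeats (the RdDM-associated compartment), and miRNA
#' hairpin loci in intergenic space. Loci on the same chromosome are kept
#' at least `min_separation` nt apart so cluster calling can recover them
#' one-to-one.
#'
#' @param pair A `genome_pair`.
#' @param annotation A `feature_annotation` from [plant_annotations()].
#' @param n_sirna21,n_sirna24,n_mirna Locus counts per class.
#' @param sirna_width,mirna_width Locus widths (nt).
#' @param min_separation Minimum gap between loci on a chromosome (nt).
#' @param seed Integer seed.
#' @return data.frame of class `sim_loci`: chrom, start, end, strand,
#'   locus_class, expression_weight, mature_offset, id.
#' @export
plant_loci <- function(pair, annotation, n_sirna21 = 20, n_sirna24 = 30,
                       n_mirna = 6, sirna_width = 150L, mirna_width = 90L,
                       min_separation = 200L, seed = 1) {
  set.seed(seed)
  lens <- nchar(pair$donor)
  promoters <- derive_promoters(annotation$genes, lens)
  host24 <- rbind(promoters[, c("chrom", "start", "end")],
                  annotation$repeats[, c("chrom", "start", "end")])
  placed <- data.frame(chrom = character(), start = integer(),
                       end = integer(), stringsAsFactors = FALSE)
  ok_sep <- function(ch, s, e) {
    same <- placed[placed$chrom == ch, , drop = FALSE]
    if (nrow(same) == 0) return(TRUE)
    all(s - same$end >= min_separation | same$start - e >= min_separation)
  }
  place_in <- function(hosts, width, n, class, strand_mode) {
    hosts <- hosts[hosts$end - hosts$start >= width, , drop = FALSE]
    if (nrow(hosts) == 0 && n > 0) {
      stop_arg("no host feature wide enough for class ", class)
    }
    out <- vector("list", n)
    for (i in seq_len(n)) {
      done <- FALSE
      for (try in seq_len(500)) {
        h <- hosts[sample(nrow(hosts), 1), ]
        s <- h$start + floor(runif(1) * (h$end - h$start - width + 1))
        e <- s + width
        if (ok_sep(h$chrom, s, e)) {
          st <- if (strand_mode == "fixed") sample(c("+", "-"), 1) else "."
          out[[i]] <- data.frame(chrom = h$chrom, start = as.integer(s),
                                 end = as.integer(e), strand = st,
                                 locus_class = class,
                                 stringsAsFactors = FALSE)
          placed <<- rbind(placed, out[[i]][, c("chrom", "start", "end")])
          done <- TRUE
          break
        }
      }
      if (!done) stop_arg("could not place ", class,
                          " locus respecting min_separation; reduce counts")
    }
    do.call(rbind, out)
  }
  loci21 <- if (n_sirna21 > 0) {
    place_in(annotation$genes, sirna_width, n_sirna21, "siRNA21", "both")
  }
  loci24 <- if (n_sirna24 > 0) {
    place_in(host24, sirna_width, n_sirna24, "siRNA24", "both")
  }
  # intergenic space for miRNA hairpins: complement of all features
  locim <- if (n_mirna > 0) {
    gaps <- list()
    for (ch in names(lens)) {
      feats <- rbind(annotation$genes[annotation$genes$chrom == ch,
                                      c("start", "end")],
                     annotation$repeats[annotation$repeats$chrom == ch,
                                        c("start", "end")],
                     promoters[promoters$chrom == ch, c("start", "end")])
      ir <- IRanges::reduce(IRanges::IRanges(feats$start + 1L, feats$end))
      gap <- IRanges::gaps(ir, start = 1L, end = lens[[ch]])
      gd <- data.frame(chrom = ch,
                       start = IRanges::start(gap) - 1L,
                       end = IRanges::end(gap))
      gaps[[ch]] <- gd[gd$end - gd$start >= mirna_width + 2L * min_separation, ]
    }
    place_in(do.call(rbind, gaps), mirna_width, n_mirna,
             "miRNA_hairpin", "fixed")
  }
  loci <- rbind(loci21, loci24, locim)
  # siRNA loci are double-stranded sources; miRNA loci keep their strand
  loci$strand[loci$locus_class != "miRNA_hairpin"] <- "."
  loci$expression_weight <- runif(nrow(loci), 0.5, 2)
  loci$mature_offset <- ifelse(loci$locus_class == "miRNA_hairpin", 15L, NA_integer_)
  loci$id <- sprintf("locus_%04d", seq_len(nrow(loci)))
  rownames(loci) <- NULL
  class(loci) <- c("sim_loci", "data.frame")
  loci
}

#' Extract hairpin sequences of planted miRNA loci
#'
#' Returns, per miRNA locus, the locus-strand genomic sequence — the
#' database [match_known_mirna()] consumes.
#'
#' @param pair A `genome_pair`.
#' @param loci A `sim_loci` table.
#' @param genome `"donor"` or `"receptor"`.
#' @return Named character vector of hairpin sequences.
#' @export
hairpin_sequences <- function(pair, loci, genome = "receptor") {
  mi <- loci[loci$locus_class == "miRNA_hairpin", , drop = FALSE]
  if (nrow(mi) == 0) return(setNames(character(), character()))
  g <- pair[[genome]]
  seqs <- substring(g[mi$chrom], mi$start + 1L, mi$end)
  seqs <- ifelse(mi$strand == "-", revcomp(seqs), seqs)
  setNames(seqs, mi$id)
}

#' Simulate a compartment's small RNA library
#'
#' Each read is a (possibly error-mutated) substring of its source genome
#' at its source locus, 3'-extended with the sequencing adapter and padded
#' with random bases up to the machine read length. Mobile reads are
#' drawn from the other compartment's genome at rate `mobile_fraction`
#' (same locus coordinates — homologous loci expressed in both partners).
#' Contaminant reads are substrings of the contaminant references.
#' Replicate labels are assigned round-robin.
#'
#' @param pair A `genome_pair`.
#' @param loci A `sim_loci` table.
#' @param compartment `"receptor"` (library native to the receptor genome)
#'   or `"donor"`.
#' @param n_reads Total reads across all replicates.
#' @param mobile_fraction Probability a non-contaminant read originates
#'   from the other compartment's genome.
#' @param error_rate Per-base substitution probability.
#' @param n_replicates Number of replicate labels (round-robin).
#' @param adapter 3' adapter sequence appended to each insert.
#' @param contaminant_fraction Fraction of reads drawn from
#'   `contaminants`.
#' @param contaminants Named character vector of contaminant reference
#'   sequences (rRNA/tRNA/chloroplast stand-ins); required when
#'   `contaminant_fraction > 0`.
#' @param machine_read_length Sequencer read length (nt).
#' @param length_jitter_prob Probability a read is 1 nt longer/shorter
#'   than its class length.
#' @param seed Integer seed; output (including FASTQ written from it) is
#'   bit-identical per seed.
#' @return List with `reads` (data.frame id, sequence, replicate; raw
#'   machine-length sequences) and `truth` (data.frame read_id,
#'   source_genome, chrom, start, end, strand, source_locus, is_mobile,
#'   spans_snp, n_errors).
#' @export
simulate_reads <- function(pair, loci, compartment = c("receptor", "donor"),
                           n_reads = 10000, mobile_fraction = 0,
                           error_rate = 0, n_replicates = 3,
                           adapter = DEFAULT_ADAPTER,
                           contaminant_fraction = 0, contaminants = NULL,
                           machine_read_length = 50L,
                           length_jitter_prob = 0.1, seed = 1) {
  compartment <- match.arg(compartment)
  if (is.null(loci) || nrow(loci) == 0) stop_arg("loci must be non-empty")
  for (f in c(mobile_fraction, error_rate, contaminant_fraction)) {
    if (f < 0 || f > 1) stop_arg("fractions must be in [0, 1]")
  }
  if (contaminant_fraction > 0 && is.null(contaminants)) {
    stop_arg("contaminants required when contaminant_fraction > 0")
  }
  set.seed(seed)
  native <- if (compartment == "receptor") pair$receptor else pair$donor
  foreign <- if (compartment == "receptor") pair$donor else pair$receptor

  is_contam <- runif(n_reads) < contaminant_fraction
  is_mobile <- !is_contam & (runif(n_reads) < mobile_fraction)

  class_len <- c(siRNA21 = 21L, siRNA24 = 24L, miRNA_hairpin = 21L)
  n <- n_reads
  chrom <- character(n); start <- integer(n); rlen <- integer(n)
  strand <- character(n); src <- character(n); locus_id <- character(n)

  gi <- which(!is_contam)
  if (length(gi)) {
    li <- sample(nrow(loci), length(gi), replace = TRUE,
                 prob = loci$expression_weight)
    L <- loci[li, ]
    len0 <- class_len[L$locus_class]
    jit <- ifelse(runif(length(gi)) < length_jitter_prob,
                  sample(c(-1L, 1L), length(gi), replace = TRUE), 0L)
    len <- pmax(len0 + jit, 17L)
    is_mi <- L$locus_class == "miRNA_hairpin"
    s <- integer(length(gi))
    s[is_mi] <- L$start[is_mi] + L$mature_offset[is_mi]
    s[!is_mi] <- L$start[!is_mi] +
      floor(runif(sum(!is_mi)) * (L$end[!is_mi] - L$start[!is_mi] - len[!is_mi] + 1))
    st <- character(length(gi))
    st[is_mi] <- L$strand[is_mi]
    st[!is_mi] <- sample(c("+", "-"), sum(!is_mi), replace = TRUE)
    chrom[gi] <- L$chrom; start[gi] <- s; rlen[gi] <- len
    strand[gi] <- st; locus_id[gi] <- L$id
    src[gi] <- ifelse(is_mobile[gi],
                      if (compartment == "receptor") "donor" else "receptor",
                      compartment)
  }
  ci <- which(is_contam)
  if (length(ci)) {
    ridx <- sample(length(contaminants), length(ci), replace = TRUE,
                   prob = nchar(contaminants))
    clen <- sample(19:25, length(ci), replace = TRUE)
    clen <- pmin(clen, nchar(contaminants)[ridx])
    cstart <- floor(runif(length(ci)) * (nchar(contaminants)[ridx] - clen + 1))
    chrom[ci] <- names(contaminants)[ridx]
    start[ci] <- as.integer(cstart); rlen[ci] <- clen
    strand[ci] <- sample(c("+", "-"), length(ci), replace = TRUE)
    src[ci] <- "contaminant"; locus_id[ci] <- NA_character_
  }

  # pull sequences from the right genome
  seqs <- character(n)
  for (g in c("native", "foreign", "contaminant")) {
    pool <- switch(g, native = native, foreign = foreign,
                   contaminant = contaminants)
    sel <- switch(g,
                  native = !is_contam & !is_mobile,
                  foreign = is_mobile,
                  contaminant = is_contam)
    if (!any(sel)) next
    src_name <- switch(g,
                       native = compartment,
                       foreign = if (compartment == "receptor") "donor" else "receptor",
                       contaminant = "contaminant")
    seqs[sel] <- substring(pool[chrom[sel]], start[sel] + 1L,
                           start[sel] + rlen[sel])
  }
  neg <- strand == "-"
  if (any(neg)) seqs[neg] <- revcomp(seqs[neg])

  # substitution errors
  n_errors <- integer(n)
  if (error_rate > 0) {
    k <- rbinom(n, rlen, error_rate)
    for (i in which(k > 0)) {
      pos <- sample(rlen[i], k[i])
      chars <- strsplit(seqs[i], "")[[1]]
      bases <- c("A", "C", "G", "T")
      for (p in pos) {
        chars[p] <- sample(setdiff(bases, chars[p]), 1)
      }
      seqs[i] <- paste(chars, collapse = "")
      n_errors[i] <- k[i]
    }
  }

  # does the source interval overlap >= 1 SNP?
  spans_snp <- logical(n)
  snp <- pair$snp_table
  if (!is.null(snp) && nrow(snp)) {
    for (ch in unique(chrom[!is_contam])) {
      pos <- sort(snp$pos[snp$chrom == ch])
      sel <- which(chrom == ch & !is_contam)
      if (!length(pos) || !length(sel)) next
      hi <- findInterval(start[sel] + rlen[sel] - 1L, pos)
      lo <- findInterval(start[sel] - 1L, pos)
      spans_snp[sel] <- hi > lo
    }
  }

  # 3' adapter + random fill up to machine read length
  raw <- paste0(seqs, adapter)
  short <- nchar(raw) < machine_read_length
  if (any(short)) {
    fill <- vapply(machine_read_length - nchar(raw[short]), function(k) {
      paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
    }, character(1))
    raw[short] <- paste0(raw[short], fill)
  }
  raw <- substr(raw, 1L, machine_read_length)

  ids <- sprintf("%s_r%07d", substr(compartment, 1, 3), seq_len(n))
  replicate <- rep_len(sprintf("rep%d", seq_len(n_replicates)), n)
  list(
    reads = data.frame(id = ids, sequence = raw, replicate = replicate,
                       stringsAsFactors = FALSE),
    truth = data.frame(read_id = ids, source_genome = src, chrom = chrom,
                       start = start, end = start + rlen, strand = strand,
                       source_locus = locus_id, is_mobile = is_mobile,
                       spans_snp = spans_snp, n_errors = n_errors,
                       stringsAsFactors = FALSE)
  )
}

#' Simulate contaminant reference sequences (rRNA/tRNA/chloroplast
#' stand-ins)
#'
#' Random sequences, synthetic — they model only the property the
#' decontamination step exploits (reads occurring exactly within them).
#'
#' @param n Number of reference sequences.
#' @param length Length of each (nt).
#' @param seed Integer seed.
#' @return Named character vector.
#' @export
simulate_contaminants <- function(n = 5, length = 2000, seed = 1) {
  set.seed(seed)
  setNames(
    vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
            collapse = "")
    }, character(1)),
    sprintf("contam_%02d", seq_len(n))
  )
}
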