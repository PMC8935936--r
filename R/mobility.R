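# Two-step SNP-discriminative classification of graft-compartment reads.
#
# Step 1: reads occurring exactly (either strand) in the receptor
# compartment's own genome are native. Step 2: reads failing step 1 that
# occur exactly in the donor genome are mobile — they can only be
# explained by transport across the graft junction. Everything else is
# unassigned. Step-1 precedence is strict: a read exact in both genomes
# (spanning no diagnostic SNP) is native, never mobile, so detection is
# restricted to SNP-spanning reads and true exchange rates are
# underestimated by construction.

#' Classify reads as native, mobile or unassigned
#'
#' @param reads Preprocessed read data.frame (id, sequence, replicate).
#' @param receptor_index `exact_index` of the receptor compartment's own
#'   genome.
#' @param donor_index `exact_index` of the graft partner's genome.
#' @param direction Label recorded in the report, e.g.
#'   `"scion_to_rootstock"`.
#' @return List of class `mobility_report`: `labels` (read_id, label),
#'   `direction`, counts `n_total`, `n_native`, `n_unmapped_step1`,
#'   `n_mobile`, `n_unassigned`.
#' @export
classify_reads <- function(reads, receptor_index, donor_index,
                           direction = "scion_to_rootstock") {
  reads <- as_read_df(reads)
  step1 <- map_readset(receptor_index, reads, map_params("all"))
  native_ids <- step1$mapped_ids
  rest <- reads[reads$id %in% step1$unmapped_ids, , drop = FALSE]
  if (nrow(rest)) {
    step2 <- map_readset(donor_index, rest, map_params("all"))
    mobile_ids <- step2$mapped_ids
    unassigned_ids <- step2$unmapped_ids
  } else {
    mobile_ids <- character()
    unassigned_ids <- character()
  }
  labels <- data.frame(
    read_id = c(native_ids, mobile_ids, unassigned_ids),
    label = c(rep("native", length(native_ids)),
              rep("mobile", length(mobile_ids)),
              rep("unassigned", length(unassigned_ids))),
    stringsAsFactors = FALSE)
  labels <- labels[match(reads$id, labels$read_id), ]
  rownames(labels) <- NULL
  structure(list(
    labels = labels,
    direction = direction,
    n_total = nrow(reads),
    n_native = length(native_ids),
    n_unmapped_step1 = length(mobile_ids) + length(unassigned_ids),
    n_mobile = length(mobile_ids),
    n_unassigned = length(unassigned_ids)
  ), class = "mobility_report")
}

#' Call clusters of mobile reads on the donor genome
#'
#' Mobile-labeled reads are placed on the donor genome and clustered with
#' the standard cluster caller; dicer calling and (optionally) known-
#' miRNA matching are applied.
#'
#' @param reads Read data.frame the labels refer to.
#' @param report A `mobility_report` from [classify_reads()].
#' @param donor_index `exact_index` of the donor genome.
#' @param params A `cluster_params`.
#' @param mparams A `map_params` for placement of the mobile reads.
#' @param hairpin_db Optional hairpin database for miRNA matching.
#' @return A `cluster_set` of mobile clusters on the donor genome.
#' @export
call_mobile_clusters <- function(reads, report, donor_index,
                                 params = cluster_params(),
                                 mparams = map_params(),
                                 hairpin_db = NULL) {
  reads <- as_read_df(reads)
  mob_ids <- report$labels$read_id[report$labels$label == "mobile" &
                                     !is.na(report$labels$label)]
  mob <- reads[reads$id %in% mob_ids, , drop = FALSE]
  if (nrow(mob) == 0) {
    return(build_clusters(data.frame(read_id = character(),
                                     chrom = character(), start = integer(),
                                     end = integer(), strand = character(),
                                     n_occurrences = integer(),
                                     replicate = character())[0, ],
                          params, total_mapped_reads = 0L))
  }
  mp <- map_readset(donor_index, mob, mparams)
  cs <- build_clusters(mp$placements, params,
                       total_mapped_reads = nrow(mp$placements))
  cs <- call_dicer(cs)
  if (!is.null(hairpin_db) && nrow(cs$clusters)) {
    cs <- match_known_mirna(cs, mob, hairpin_db)
  }
  cs
}

#' Summarize a mobility report as fractions and size-class counts
#'
#' Percentages are reported both raw and rounded half-up to one decimal
#' place. Zero denominators yield 0 with `empty_input = TRUE`.
#'
#' @param report A `mobility_report`.
#' @param mobile_clusters Optional `cluster_set` of mobile clusters; adds
#'   per-size-class cluster counts.
#' @return List with percentage fields (`pct_native`, `pct_unmapped`,
#'   `pct_mobile_of_unmapped`, and `_raw` variants), the input counts,
#'   and `size_class_counts` when clusters are supplied.
#' @export
summarize_mobility <- function(report, mobile_clusters = NULL) {
  empty <- report$n_total == 0
  pn <- if (empty) 0 else pct_of(report$n_native, report$n_total)
  pu <- if (empty) 0 else pct_of(report$n_unmapped_step1, report$n_total)
  pm <- if (report$n_unmapped_step1 == 0) 0 else
    pct_of(report$n_mobile, report$n_unmapped_step1)
  out <- list(
    direction = report$direction,
    n_total = report$n_total,
    n_native = report$n_native,
    n_unmapped_step1 = report$n_unmapped_step1,
    n_mobile = report$n_mobile,
    n_unassigned = report$n_unassigned,
    pct_native_raw = pn, pct_native = round_half_up(pn, 1),
    pct_unmapped_raw = pu, pct_unmapped = round_half_up(pu, 1),
    pct_mobile_of_unmapped_raw = pm,
    pct_mobile_of_unmapped = round_half_up(pm, 1),
    empty_input = empty
  )
  if (!is.null(mobile_clusters)) {
    out$size_class_counts <- mobile_class_summary(mobile_clusters)
  }
  out
}

#' Tabulate mobile clusters by size class
#'
#' @param cluster_set A `cluster_set` (dicer-called).
#' @return List: `total`, `n_mirna`, per-class counts `by_class` (named
#'   20..24), per-class percentages of the total (1 d.p.).
#' @export
mobile_class_summary <- function(cluster_set) {
  cl <- cluster_set$clusters
  dicer <- cl[!is.na(cl$dicer_call) & cl$dicer_call, , drop = FALSE]
  classes <- 20:24
  by_class <- vapply(classes, function(k) sum(dicer$size_class == k,
                                              na.rm = TRUE), integer(1))
  names(by_class) <- as.character(classes)
  total <- nrow(dicer)
  pct <- if (total > 0) round_half_up(by_class / total * 100, 1) else
    setNames(rep(0, length(classes)), names(by_class))
  list(total = total,
       n_mirna = sum(!is.na(dicer$mirna_match)),
       by_class = by_class,
       pct_by_class = pct)
}

#' Fraction of possible reads the SNP table makes detectable
#'
#' Diagnostic for the detection limit: among truth-mobile reads (when a
#' simulation truth table is available), only those spanning >= 1 SNP can
#' fail step 1 and be recovered as mobile.
#'
#' @param truth SimTruth data.frame from [simulate_reads()].
#' @return Fraction of truth-mobile reads that span a SNP (NA if no
#'   mobile reads).
#' @export
snp_spanning_detectable_fraction <- function(truth) {
  mob <- truth[truth$is_mobile, , drop = FALSE]
  if (nrow(mob) == 0) return(NA_real_)
  mean(mob$spans_snp)
}
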