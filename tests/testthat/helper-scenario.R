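# Small shared synthetic scenario built in code at test time.

tiny_scenario <- function(seed = 11, snp_rate = 0.005, n_reads = 4000,
                          mobile_fraction = 0.05, error_rate = 0,
                          contaminant_fraction = 0) {
  pair <- simulate_genome_pair(2, 20000, snp_rate, seed = seed)
  ann <- plant_annotations(pair, 10, 8, seed = seed + 1)
  loci <- plant_loci(pair, ann, 5, 7, 2, seed = seed + 2)
  contam <- simulate_contaminants(3, 1000, seed = seed + 3)
  sim <- simulate_reads(pair, loci, "receptor", n_reads,
                        mobile_fraction = mobile_fraction,
                        error_rate = error_rate,
                        contaminant_fraction = contaminant_fraction,
                        contaminants = contam, seed = seed + 4)
  list(pair = pair, annotation = ann, loci = loci, contam = contam,
       reads = sim$reads, truth = sim$truth)
}

# strip adapters deterministically for scenarios with error_rate = 0
clean_reads <- function(sc) {
  r <- trim_adapter(sc$reads)
  filter_length(r, 17)
}

random_seq_fixed <- function(n, seed) {
  set.seed(seed)
  random_seq(n)
}

flip_base <- function(b) c(A = "C", C = "G", G = "T", T = "A")[[b]]

as_reads <- function(x) {
  data.frame(id = names(x), sequence = unname(x),
             replicate = NA_character_, stringsAsFactors = FALSE)
}
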