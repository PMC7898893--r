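# Shared fixtures, built in code.

# Small, fast study configuration: full 58+15 design but fewer loci and
# shallower sequencing than the default study conditions.
small_config <- function(...) {
  args <- list(...)
  defaults <- list(n_loci = 10L, tissue_depth = 8000, edna_depth = 8000,
                   field_depth = 2000)
  defaults[names(args)] <- args
  do.call(sim_config, defaults)
}

# one small study shared across test files (built lazily, once)
.fixture_env <- new.env(parent = emptyenv())
shared_truth <- function() {
  if (is.null(.fixture_env$truth)) {
    .fixture_env$truth <- simulate_study(small_config(), seed = 2024L)
  }
  .fixture_env$truth
}

# random frequency vector of n alleles whose total is `total`
random_freqs <- function(n, total = 1) {
  p <- runif(n, 0.05, 1)
  p / sum(p) * total
}

# tiny read count table builder
rct <- function(sample, locus, allele, reads) {
  data.frame(sample = sample, locus = locus, allele = allele,
             reads = reads, stringsAsFactors = FALSE)
}
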