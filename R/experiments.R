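#' @title End-to-end experiments on synthetic studies
#'
#' @description
#' Three orchestrated experiments mirror the package's validation logic
#' on a [simulate_study()] data set: per-mesocosm contributor estimation
#' from pooled tissue genotypes and from eDNA under each filtering
#' scheme and both population-frequency sources; the bootstrap
#' simulated-mixture experiment; and the low-depth field trial with
#' replicate eDNA samples.  Every run returns its results together with
#' a manifest (config, seed, schemes, package version) sufficient to
#' reproduce it.
#' @name experiments
NULL

#' Default filtering schemes under study
#'
#' The three fixed read-frequency thresholds (0.001, 0.01, 0.1) plus the
#' richness-dependent variable scheme.
#'
#' @param r_min,r_max richness range for the variable scheme.
#' @return named list of [threshold_scheme()] objects.
#' @export
default_schemes <- function(r_min = 2, r_max = 21) {
  list(t0.001 = threshold_scheme("fixed", t = 0.001),
       t0.01 = threshold_scheme("fixed", t = 0.01),
       t0.1 = threshold_scheme("fixed", t = 0.1),
       variable = threshold_scheme("variable", r_min = r_min,
                                   r_max = r_max))
}

# tissue-derived population frequencies of the mesocosm individuals,
# via genotype calling from the tissue reads
tissue_pop_freqs <- function(truth, individuals) {
  counts <- truth$tissue_counts
  counts <- counts[counts$sample %in% individuals, , drop = FALSE]
  gm <- genotype_matrix(counts)
  pop_allele_freqs(gm$genotypes)
}

# richness per locus from the tissue-genotyped reference panel
panel_richness <- function(pop) {
  tab <- tapply(pop$allele, pop$locus, function(a) length(unique(a)))
  r <- as.integer(tab)
  names(r) <- names(tab)
  r
}

unit_sizes_of <- function(mesocosms) {
  tab <- table(mesocosms$unit)
  sizes <- as.integer(tab)
  names(sizes) <- names(tab)
  sizes
}

#' Per-mesocosm contributor estimation experiment
#'
#' For every mesocosm, estimates the number of contributors from (a) the
#' pooled tissue profile (union of the member individuals' called
#' genotypes) and (b) the eDNA profile under every filtering scheme,
#' each crossed with both population-frequency sources: tissue-derived
#' (genotyped mesocosm individuals) and eDNA-derived (read frequencies
#' combined across all mesocosm eDNA samples).
#'
#' @param truth a `synthetic_truth` from [simulate_study()].
#' @param schemes named list of [threshold_scheme()]s for the eDNA
#'   profiles.
#' @param x_grid candidate contributor grid.
#' @return list with `results` (one row per mesocosm x profile type x
#'   scheme x frequency source: `unit`, `true_x`, `profile`, `scheme`,
#'   `freq_source`, `x_hat`, `bias`, `boundary`, `n_dropped_alleles`)
#'   and `manifest`.
#' @export
run_mesocosm_experiment <- function(truth, schemes = default_schemes(),
                                    x_grid = 1:100) {
  stopifnot(inherits(truth, "synthetic_truth"))
  meso_ids <- sort(unique(truth$mesocosms$individual))
  pop_tissue <- tissue_pop_freqs(truth, meso_ids)
  pooled_all <- edna_pipeline(truth$edna_counts,
                              replicate_map = truth$edna_replicate_map)
  pop_edna <- edna_allele_freqs(pooled_all)
  richness <- panel_richness(pop_tissue)
  sizes <- unit_sizes_of(truth$mesocosms)
  sources <- list(tissue = pop_tissue, edna = pop_edna)
  gm_all <- genotype_matrix(
    truth$tissue_counts[truth$tissue_counts$sample %in% meso_ids, ,
                        drop = FALSE])
  rows <- list()
  for (u in names(sizes)) {
    members <- truth$mesocosms$individual[truth$mesocosms$unit == u]
    geno_u <- gm_all$genotypes[gm_all$genotypes$individual %in% members, ,
                               drop = FALSE]
    reps_u <- truth$edna_replicate_map[truth$edna_replicate_map$unit == u, ,
                                       drop = FALSE]
    counts_u <- truth$edna_counts[truth$edna_counts$sample %in%
                                    reps_u$sample, , drop = FALSE]
    for (src in names(sources)) {
      pop <- sources[[src]]
      prof_t <- genotypes_to_profile(geno_u, pop)
      est_t <- suppressWarnings(
        estimate_contributors(prof_t, pop, x_grid, true_x = sizes[[u]]))
      rows[[length(rows) + 1L]] <- data.frame(
        unit = u, true_x = sizes[[u]], profile = "tissue-pooled",
        scheme = "none", freq_source = src, x_hat = est_t$x_hat,
        bias = est_t$bias, boundary = est_t$boundary,
        n_dropped_alleles = attr(prof_t, "n_dropped_alleles"),
        stringsAsFactors = FALSE)
      for (sc in names(schemes)) {
        filt <- edna_pipeline(counts_u, replicate_map = reps_u,
                              scheme = schemes[[sc]], low_freq = NULL,
                              richness = richness)
        prof_e <- to_mixture_profile(filt, pop)
        est_e <- suppressWarnings(
          estimate_contributors(prof_e, pop, x_grid, true_x = sizes[[u]]))
        rows[[length(rows) + 1L]] <- data.frame(
          unit = u, true_x = sizes[[u]], profile = "eDNA",
          scheme = sc, freq_source = src, x_hat = est_e$x_hat,
          bias = est_e$bias, boundary = est_e$boundary,
          n_dropped_alleles = attr(prof_e, "n_dropped_alleles"),
          stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  list(results = results,
       manifest = run_manifest(truth, schemes, x_grid = range(x_grid)))
}

#' Bootstrap simulated-mixture experiment on a synthetic study
#'
#' Delegates to [bootstrap_mixture_experiment()] with the study's
#' mesocosm eDNA counts, tissue-derived population frequencies and
#' tissue-panel richness.
#'
#' @inheritParams run_mesocosm_experiment
#' @param n_reps bootstrap replicates.
#' @param draw_range mesocosms per draw.
#' @param seed seed for the bootstrap draws.
#' @return list with `results` (see [bootstrap_mixture_experiment()]),
#'   `summary` (per-scheme, per-truth mean bias) and `manifest`.
#' @export
run_bootstrap_experiment <- function(truth, schemes = default_schemes(),
                                     n_reps = 1000L, draw_range = 2:12,
                                     x_grid = 1:100, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  meso_ids <- sort(unique(truth$mesocosms$individual))
  pop_tissue <- tissue_pop_freqs(truth, meso_ids)
  richness <- panel_richness(pop_tissue)
  sizes <- unit_sizes_of(truth$mesocosms)
  results <- bootstrap_mixture_experiment(
    truth$edna_counts, truth$edna_replicate_map, sizes, pop_tissue,
    schemes, n_reps = n_reps, draw_range = draw_range, x_grid = x_grid,
    richness = richness, seed = seed)
  list(results = results, summary = bias_summary(results),
       manifest = run_manifest(truth, schemes, n_reps = n_reps,
                               draw_range = range(draw_range),
                               bootstrap_seed = seed,
                               x_grid = range(x_grid)))
}

#' Field-trial contributor estimation experiment
#'
#' Estimates the number of contributors in each replicate field eDNA
#' sample under two population-frequency sources: tissue-derived (all
#' genotyped individuals: mesocosm plus field tissue samples) and
#' eDNA-derived (read frequencies pooled across the replicate field
#' samples).  Also reports the correlation between the pooled field
#' eDNA allele frequencies and the tissue-derived reference.
#'
#' @inheritParams run_mesocosm_experiment
#' @param scheme threshold scheme applied to each replicate sample
#'   (default: the per-sample 1% filter alone, i.e. the base chain).
#' @return list with `results` (per replicate x source: `sample`,
#'   `freq_source`, `x_hat`, `boundary`, `n_dropped_alleles`),
#'   `comparison` (a `frequency_comparison` of pooled field eDNA vs
#'   tissue frequencies), `true_contributors`, and `manifest`.
#' @export
run_field_experiment <- function(truth, scheme = NULL, x_grid = 1:100) {
  stopifnot(inherits(truth, "synthetic_truth"))
  gm <- genotype_matrix(truth$tissue_counts)
  pop_tissue <- pop_allele_freqs(gm$genotypes)
  richness <- panel_richness(pop_tissue)
  field_counts <- truth$field$counts
  field_samples <- unique(field_counts$sample)
  pool_map <- data.frame(sample = field_samples, unit = "field_pooled",
                         stringsAsFactors = FALSE)
  pooled <- edna_pipeline(field_counts, replicate_map = pool_map)
  pop_edna <- edna_allele_freqs(pooled)
  comparison <- align_and_correlate(pop_edna, pop_tissue)
  sources <- list(tissue = pop_tissue, edna = pop_edna)
  rows <- list()
  for (sm in field_samples) {
    counts_s <- field_counts[field_counts$sample == sm, , drop = FALSE]
    filt <- edna_pipeline(counts_s, scheme = scheme, richness = richness)
    for (src in names(sources)) {
      prof <- to_mixture_profile(filt, sources[[src]])
      est <- suppressWarnings(
        estimate_contributors(prof, sources[[src]], x_grid))
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sm, freq_source = src, x_hat = est$x_hat,
        boundary = est$boundary,
        n_dropped_alleles = attr(prof, "n_dropped_alleles"),
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  list(results = results, comparison = comparison,
       true_contributors = truth$field$true_contributors,
       manifest = run_manifest(truth, if (is.null(scheme)) list() else
         list(scheme = scheme), x_grid = range(x_grid)))
}

run_manifest <- function(truth, schemes, ...) {
  c(list(seed = truth$seed,
         n_loci = truth$config$n_loci,
         n_individuals = truth$config$n_individuals,
         schemes = lapply(schemes, unclass),
         package_version = as.character(utils::packageVersion("ednamix")),
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    list(...))
}
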