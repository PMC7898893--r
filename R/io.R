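#' @title CSV and JSON interchange
#'
#' @description
#' Plain-text readers and writers for the package's tabular containers:
#' read count tables and scaled counts (`sample`, `locus`, `allele`,
#' `reads` / `scaled_reads`), population allele frequencies (`locus`,
#' `allele`, `freq`), mixture profiles (`locus`, `allele`), genotype
#' tables (`individual`, `locus`, `allele1`, `allele2`) and contributor
#' estimates (CSV likelihood profile plus JSON summary).
#' @name io
NULL

#' @rdname io
#' @param path file path.
#' @export
read_count_table <- function(path) {
  as_read_count_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname io
#' @param counts a read count table.
#' @export
write_count_table <- function(counts, path) {
  utils::write.csv(as_read_count_table(counts), path, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_pop_freqs <- function(path) {
  as_pop_freqs_df(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname io
#' @param pop population allele frequencies.
#' @export
write_pop_freqs <- function(pop, path) {
  utils::write.csv(as_pop_freqs_df(pop), path, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_mixture_profile <- function(path) {
  as_mixture_profile_df(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname io
#' @param profile a mixture profile.
#' @export
write_mixture_profile <- function(profile, path) {
  utils::write.csv(as_mixture_profile_df(profile)[c("locus", "allele")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_genotypes <- function(path) {
  as_genotypes_df(utils::read.csv(path, stringsAsFactors = FALSE,
                                  na.strings = c("NA", "")))
}

#' @rdname io
#' @param genotypes a genotype table.
#' @export
write_genotypes <- function(genotypes, path) {
  utils::write.csv(as_genotypes_df(genotypes), path, row.names = FALSE)
  invisible(path)
}

#' Write a contributor estimate as CSV profile + JSON summary
#'
#' @param est a `contributor_estimate`.
#' @param profile_path CSV path for the per-x log-likelihood profile.
#' @param summary_path JSON path for the scalar summary (`x_hat`,
#'   boundary flag, locus and dropped-allele accounting).
#' @return invisibly, the two paths.
#' @export
write_contributor_estimate <- function(est, profile_path, summary_path) {
  stopifnot(inherits(est, "contributor_estimate"))
  utils::write.csv(data.frame(x = est$x_grid, loglik = est$loglik),
                   profile_path, row.names = FALSE)
  summary <- list(x_hat = est$x_hat, boundary = isTRUE(est$boundary),
                  n_informative_loci = est$n_informative_loci,
                  n_skipped_loci = est$n_skipped_loci,
                  n_dropped_alleles = est$n_dropped_alleles)
  if (!is.na(est$bias)) summary$bias <- est$bias
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE)
  invisible(c(profile_path, summary_path))
}

#' Read or write a locus panel
#'
#' The panel is stored as two CSV files: `<stem>_loci.csv` and (when
#' allele sequences are known) `<stem>_alleles.csv`.
#'
#' @param panel a `locus_panel`.
#' @param stem path stem for the two CSV files.
#' @return `write_panel()`: invisibly, the paths written;
#'   `read_panel()`: a `locus_panel`.
#' @export
write_panel <- function(panel, stem) {
  loci_path <- paste0(stem, "_loci.csv")
  utils::write.csv(panel_loci_df(panel), loci_path, row.names = FALSE)
  paths <- loci_path
  alleles <- panel_alleles_df(panel)
  if (!is.null(alleles)) {
    alleles_path <- paste0(stem, "_alleles.csv")
    utils::write.csv(alleles, alleles_path, row.names = FALSE)
    paths <- c(paths, alleles_path)
  }
  invisible(paths)
}

#' @rdname write_panel
#' @export
read_panel <- function(stem) {
  loci <- utils::read.csv(paste0(stem, "_loci.csv"),
                          stringsAsFactors = FALSE)
  alleles_path <- paste0(stem, "_alleles.csv")
  alleles <- if (file.exists(alleles_path)) {
    utils::read.csv(alleles_path, stringsAsFactors = FALSE,
                    colClasses = c(allele = "character"))
  } else {
    NULL
  }
  structure(list(loci = loci, alleles = alleles), class = "locus_panel")
}
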