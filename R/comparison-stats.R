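#' @title Comparing eDNA-derived and tissue-derived allele frequencies
#'
#' @description
#' Agreement between two allele-frequency estimates is quantified over
#' the per-locus union of alleles (an allele absent from one source is
#' paired with frequency 0): an overall Pearson correlation across all
#' alleles and loci, and per-locus correlations.  Sample-level structure
#' is summarised by PCA on scaled and centred allele-frequency vectors
#' with Euclidean distances over all axes.  The bootstrap mixture
#' experiment combines eDNA read counts from several mesocosms into
#' simulated mixtures of known contributor counts and measures the bias
#' of the estimated number of contributors under each filtering scheme.
#' @name comparison_stats
NULL

#' Align two allele-frequency sets and correlate them
#'
#' @param f1,f2 allele frequencies (`locus`, `allele`, `freq`); `f1` and
#'   `f2` need not list the same alleles.
#' @param min_locus_alleles minimum union-allele count for a per-locus
#'   correlation to be reported (below it the correlation is degenerate:
#'   two-allele loci always give exactly +/-1).
#' @return a `frequency_comparison` list: `aligned` (locus, allele,
#'   freq1, freq2), `overall_r`, and `per_locus` (locus, n_alleles, r;
#'   `r` is NA for loci below the union threshold or without variance).
#' @export
align_and_correlate <- function(f1, f2, min_locus_alleles = 3L) {
  f1 <- as.data.frame(f1)
  f2 <- as.data.frame(f2)
  key1 <- paste(f1$locus, f1$allele, sep = "\r")
  key2 <- paste(f2$locus, f2$allele, sep = "\r")
  all_keys <- union(key1, key2)
  parts <- do.call(rbind, strsplit(all_keys, "\r", fixed = TRUE))
  aligned <- data.frame(locus = parts[, 1], allele = parts[, 2],
                        freq1 = f1$freq[match(all_keys, key1)],
                        freq2 = f2$freq[match(all_keys, key2)],
                        stringsAsFactors = FALSE)
  aligned$freq1[is.na(aligned$freq1)] <- 0
  aligned$freq2[is.na(aligned$freq2)] <- 0
  aligned <- aligned[order(aligned$locus, aligned$allele), ]
  rownames(aligned) <- NULL
  if (nrow(aligned) < 2L) {
    stop("need at least two aligned allele entries", call. = FALSE)
  }
  overall_r <- if (stats::sd(aligned$freq1) == 0 ||
                   stats::sd(aligned$freq2) == 0) {
    NA_real_
  } else {
    stats::cor(aligned$freq1, aligned$freq2)
  }
  per_locus <- do.call(rbind, lapply(split(aligned, aligned$locus),
                                     function(d) {
    r <- NA_real_
    if (nrow(d) >= min_locus_alleles &&
        stats::sd(d$freq1) > 0 && stats::sd(d$freq2) > 0) {
      r <- stats::cor(d$freq1, d$freq2)
    }
    data.frame(locus = d$locus[1], n_alleles = nrow(d), r = r,
               stringsAsFactors = FALSE)
  }))
  rownames(per_locus) <- NULL
  structure(list(aligned = aligned, overall_r = overall_r,
                 per_locus = per_locus),
            class = "frequency_comparison")
}

#' @export
print.frequency_comparison <- function(x, ...) {
  cat("Allele-frequency comparison over", nrow(x$aligned),
      "aligned alleles\n")
  cat("  overall Pearson r:", round(x$overall_r, 4), "\n")
  r <- x$per_locus$r[!is.na(x$per_locus$r)]
  if (length(r)) {
    cat("  per-locus r: ", round(min(r), 3), "-", round(max(r), 3),
        " (", length(r), " loci)\n", sep = "")
  }
  invisible(x)
}

#' Build a samples x alleles frequency matrix
#'
#' @param freq_list named list of allele-frequency data frames, one per
#'   sample; columns are the union of `locus:allele` combinations,
#'   absent alleles filled with 0.
#' @return numeric matrix, rows = samples.
#' @export
freqs_matrix <- function(freq_list) {
  keys <- unique(unlist(lapply(freq_list, function(f) {
    paste(f$locus, f$allele, sep = ":")
  })))
  keys <- sort(keys)
  m <- matrix(0, length(freq_list), length(keys),
              dimnames = list(names(freq_list), keys))
  for (i in seq_along(freq_list)) {
    f <- freq_list[[i]]
    m[i, paste(f$locus, f$allele, sep = ":")] <- f$freq
  }
  m
}

#' PCA ordination of samples by allele frequencies
#'
#' Columns are centred to mean 0 and scaled to unit variance
#' (zero-variance columns are dropped first); scores come from the
#' singular value decomposition and all axes are retained, so Euclidean
#' distances between score rows equal distances between the
#' scaled-centred data rows exactly.
#'
#' @param freq_matrix samples x alleles matrix (see [freqs_matrix()]).
#' @return a `sample_ordination` list: `scores` (samples x PCs),
#'   `explained_var` (share per axis), `dist` (full Euclidean distance
#'   matrix), `n_dropped_columns`.
#' @export
pca_samples <- function(freq_matrix) {
  if (nrow(freq_matrix) < 2L) {
    stop("PCA needs at least two samples", call. = FALSE)
  }
  v <- apply(freq_matrix, 2, stats::var)
  dropped <- sum(v == 0)
  m <- freq_matrix[, v > 0, drop = FALSE]
  if (ncol(m) < 2L) {
    stop("fewer than two variable columns; ordination impossible",
         call. = FALSE)
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  d <- as.matrix(stats::dist(pc$x))
  structure(list(scores = pc$x, explained_var = ev, dist = d,
                 n_dropped_columns = dropped),
            class = "sample_ordination")
}

#' Bootstrap simulated-mixture contributor experiment
#'
#' Each replicate draws a uniform number of mesocosms (without
#' replacement) from `draw_range`, combines their raw eDNA read counts
#' into one simulated mixture, applies the full filtering chain under
#' each threshold scheme, and estimates the number of contributors.
#' The truth is the total number of fish in the drawn mesocosms.
#'
#' @param edna_counts raw eDNA read count table for all mesocosm
#'   replicate samples.
#' @param replicate_map data frame (`sample`, `unit`) mapping replicate
#'   samples to mesocosms.
#' @param unit_sizes named numeric vector: mesocosm unit -> number of
#'   fish.
#' @param pop population allele frequencies used for estimation.
#' @param schemes named list of [threshold_scheme()] objects.
#' @param n_reps bootstrap replicates per scheme.
#' @param draw_range range of mesocosms per draw.
#' @param x_grid candidate contributor grid; must cover the largest
#'   possible truth.
#' @param richness per-locus richness for variable schemes.
#' @param min_reads,low_freq passed to [edna_pipeline()]; the per-sample
#'   low-frequency filter defaults to off here because the scheme under
#'   study is the frequency filter.
#' @param seed integer seed; results are reproducible from it.
#' @return data frame with one row per (replicate, scheme): `replicate`,
#'   `scheme`, `n_mesocosms`, `units`, `true_x`, `x_hat`, `bias`,
#'   `boundary`.
#' @export
bootstrap_mixture_experiment <- function(edna_counts, replicate_map,
                                         unit_sizes, pop, schemes,
                                         n_reps = 1000L, draw_range = 2:12,
                                         x_grid = 1:100, richness = NULL,
                                         min_reads = 10, low_freq = NULL,
                                         seed = 1L) {
  stopifnot(is.list(schemes), length(schemes) > 0)
  if (is.null(names(schemes))) {
    names(schemes) <- paste0("scheme", seq_along(schemes))
  }
  units <- unique(replicate_map$unit)
  if (max(draw_range) > length(units)) {
    stop("draw size ", max(draw_range), " exceeds available mesocosms (",
         length(units), ")", call. = FALSE)
  }
  if (!all(units %in% names(unit_sizes))) {
    stop("unit_sizes must name every mesocosm unit", call. = FALSE)
  }
  edna_counts <- as_read_count_table(edna_counts)
  counts_by_unit <- split(
    edna_counts,
    replicate_map$unit[match(edna_counts$sample, replicate_map$sample)])
  withr::with_seed(seed, {
    rows <- list()
    for (rep_i in seq_len(n_reps)) {
      k <- if (length(draw_range) == 1L) draw_range else
        sample(draw_range, 1L)
      drawn <- sample(units, k)
      mix <- do.call(rbind, counts_by_unit[drawn])
      mix <- aggregate(reads ~ locus + allele, data = mix, FUN = sum)
      mix$sample <- "mixture"
      true_x <- sum(unit_sizes[drawn])
      for (sc in names(schemes)) {
        filtered <- edna_pipeline(mix, scheme = schemes[[sc]],
                                  min_reads = min_reads,
                                  low_freq = low_freq,
                                  richness = richness)
        prof <- to_mixture_profile(filtered, pop)
        est <- suppressWarnings(
          estimate_contributors(prof, pop, x_grid, true_x = true_x))
        rows[[length(rows) + 1L]] <- data.frame(
          replicate = rep_i, scheme = sc, n_mesocosms = k,
          units = paste(sort(drawn), collapse = "+"), true_x = true_x,
          x_hat = est$x_hat, bias = est$bias, boundary = est$boundary,
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Summarise contributor-estimation bias
#'
#' @param results a bootstrap or mesocosm result table holding `scheme`,
#'   `true_x` and `bias` columns.
#' @param truth_breaks optional cut points grouping `true_x` into bins;
#'   `NULL` keeps each truth value separate.
#' @return data frame per (scheme, truth bin): `n`, `mean_bias`,
#'   `sd_bias`, `mean_x_hat`.
#' @export
bias_summary <- function(results, truth_breaks = NULL) {
  stopifnot(all(c("scheme", "true_x", "bias") %in% names(results)))
  grp <- if (is.null(truth_breaks)) {
    factor(results$true_x)
  } else {
    cut(results$true_x, truth_breaks, include.lowest = TRUE)
  }
  key <- interaction(results$scheme, grp, drop = TRUE, sep = "\r")
  out <- do.call(rbind, lapply(split(results, key), function(d) {
    data.frame(scheme = d$scheme[1],
               truth = if (is.null(truth_breaks)) as.character(d$true_x[1])
                       else as.character(cut(d$true_x[1], truth_breaks,
                                             include.lowest = TRUE)),
               n = nrow(d), mean_bias = mean(d$bias),
               sd_bias = stats::sd(d$bias),
               mean_x_hat = mean(d$true_x + d$bias),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$scheme, suppressWarnings(as.numeric(out$truth)),
                   out$truth), ]
  rownames(out) <- NULL
  out
}
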