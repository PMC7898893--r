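#' @title eDNA read-count filtering, scaling and pooling
#'
#' @description
#' eDNA amplicon sequencing yields per-sample, per-locus, per-allele read
#' counts that mix true alleles with PCR stutter and sequencing error.
#' These functions implement the fixed processing chain used throughout
#' the package:
#' minimum-read filter, scaling to 100 reads per locus and sample,
#' low-frequency filter, pooling of replicate water samples, and either
#' read-frequency allele-frequency estimation or threshold filtering into
#' a mixture profile.  [edna_pipeline()] composes the stages in that
#' order; the individual stages are exported for inspection and testing.
#' @name edna_alleles
NULL

as_read_count_table <- function(counts) {
  counts <- as.data.frame(counts)
  need <- c("sample", "locus", "allele", "reads")
  if (!all(need %in% names(counts))) {
    stop("a read count table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  counts$sample <- as.character(counts$sample)
  counts$locus <- as.character(counts$locus)
  counts$allele <- as.character(counts$allele)
  if (any(counts$reads < 0)) stop("read counts must be >= 0", call. = FALSE)
  if (anyDuplicated(counts[c("sample", "locus", "allele")])) {
    stop("duplicate (sample, locus, allele) rows in read count table",
         call. = FALSE)
  }
  counts[need]
}

as_scaled_counts <- function(scaled) {
  scaled <- as.data.frame(scaled)
  need <- c("sample", "locus", "allele", "scaled_reads")
  if (!all(need %in% names(scaled))) {
    stop("scaled counts need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  scaled
}

#' Remove alleles with too few reads in a sample
#'
#' Alleles observed with fewer than `min_reads` reads in a sample are
#' treated as unreliable detections and removed, per sample.
#'
#' @param counts read count table: data frame with columns `sample`,
#'   `locus`, `allele`, `reads`.
#' @param min_reads minimum read count for an allele to be retained
#'   (boundary inclusive: exactly `min_reads` reads are kept).
#' @return the filtered read count table.
#' @export
min_read_filter <- function(counts, min_reads = 10) {
  counts <- as_read_count_table(counts)
  out <- counts[counts$reads >= min_reads, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scale read counts to 100 reads per sample and locus
#'
#' Within each (sample, locus), counts are rescaled so they sum to 100,
#' removing between-sample differences in sequencing depth before
#' frequency-based filters are applied.  Scaled counts are kept as reals:
#' rounding at this depth would erase sub-1% alleles before any
#' frequency filter could act on them.
#'
#' @inheritParams min_read_filter
#' @return data frame with columns `sample`, `locus`, `allele`,
#'   `scaled_reads`; (sample, locus) groups with zero total reads are
#'   omitted.
#' @export
scale_to_100 <- function(counts) {
  counts <- as_read_count_table(counts)
  if (nrow(counts) == 0L) {
    return(data.frame(sample = character(), locus = character(),
                      allele = character(), scaled_reads = numeric()))
  }
  key <- paste(counts$sample, counts$locus, sep = "\r")
  tot <- ave(counts$reads, key, FUN = sum)
  keep <- tot > 0
  out <- data.frame(sample = counts$sample[keep], locus = counts$locus[keep],
                    allele = counts$allele[keep],
                    scaled_reads = 100 * counts$reads[keep] / tot[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Remove low-frequency alleles within each sample and locus
#'
#' Alleles whose within-(sample, locus) read frequency is below `min_freq`
#' are removed; they are the typical signature of PCR stutter and
#' sequencing error.  Surviving scaled counts are deliberately not
#' re-scaled: read frequencies are recomputed from surviving counts at
#' frequency-estimation time.
#'
#' @param scaled scaled counts as produced by [scale_to_100()].
#' @param min_freq frequency below which alleles are removed (boundary
#'   exclusive: exactly `min_freq` is kept).
#' @return filtered scaled counts.
#' @export
low_freq_filter <- function(scaled, min_freq = 0.01) {
  scaled <- as_scaled_counts(scaled)
  if (nrow(scaled) == 0L) return(scaled)
  key <- paste(scaled$sample, scaled$locus, sep = "\r")
  tot <- ave(scaled$scaled_reads, key, FUN = sum)
  out <- scaled[scaled$scaled_reads / tot >= min_freq, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pool replicate samples into one pseudo-sample per unit
#'
#' Sums scaled read counts across replicate samples of the same unit
#' (e.g. duplicate water samples from one mesocosm).  Loci present in
#' only some replicates contribute their counts from those replicates
#' alone (the union of loci is taken).
#'
#' @inheritParams low_freq_filter
#' @param replicate_map data frame with columns `sample`, `unit` mapping
#'   every sample to its pooling unit.  Samples missing from the map
#'   raise an error.
#' @return scaled counts with `sample` replaced by the unit identifier.
#' @export
pool_replicates <- function(scaled, replicate_map) {
  scaled <- as_scaled_counts(scaled)
  replicate_map <- as.data.frame(replicate_map)
  if (!all(c("sample", "unit") %in% names(replicate_map))) {
    stop("replicate_map needs columns 'sample' and 'unit'", call. = FALSE)
  }
  if (nrow(scaled) == 0L) {
    return(data.frame(sample = character(), locus = character(),
                      allele = character(), scaled_reads = numeric()))
  }
  unit <- replicate_map$unit[match(scaled$sample, replicate_map$sample)]
  if (anyNA(unit)) {
    stop("samples without a pooling unit: ",
         paste(unique(scaled$sample[is.na(unit)]), collapse = ", "),
         call. = FALSE)
  }
  agg <- aggregate(scaled_reads ~ unit + locus + allele,
                   data = cbind(scaled, unit = as.character(unit)), FUN = sum)
  out <- data.frame(sample = agg$unit, locus = agg$locus,
                    allele = agg$allele, scaled_reads = agg$scaled_reads,
                    stringsAsFactors = FALSE)
  out <- out[order(out$sample, out$locus, out$allele), ]
  rownames(out) <- NULL
  out
}

#' Allele frequencies from pooled eDNA read counts
#'
#' Estimates allele frequencies directly as read frequencies: within each
#' locus, an allele's frequency is its scaled read count divided by the
#' locus total.  When the input holds several samples or units their
#' scaled counts are combined first, so the result represents the pooled
#' material.
#'
#' @param pooled scaled counts (typically after [pool_replicates()]).
#' @return population allele frequencies: data frame with columns
#'   `locus`, `allele`, `freq`; per-locus frequencies sum to 1.  Loci
#'   with no surviving reads are absent.
#' @export
edna_allele_freqs <- function(pooled) {
  pooled <- as_scaled_counts(pooled)
  if (nrow(pooled) == 0L) {
    return(data.frame(locus = character(), allele = character(),
                      freq = numeric()))
  }
  agg <- aggregate(scaled_reads ~ locus + allele, data = pooled, FUN = sum)
  tot <- ave(agg$scaled_reads, agg$locus, FUN = sum)
  out <- data.frame(locus = agg$locus, allele = agg$allele,
                    freq = agg$scaled_reads / tot, stringsAsFactors = FALSE)
  out <- out[out$freq > 0, , drop = FALSE]
  out <- out[order(out$locus, out$allele), ]
  rownames(out) <- NULL
  out
}

#' Construct a frequency-threshold filtering scheme
#'
#' Fixed schemes remove alleles below a single read-frequency threshold.
#' The variable scheme adapts the threshold to per-locus allelic
#' richness: species-rich loci carry genuinely rare alleles, so their
#' threshold is relaxed from `t_max` down to `t_min` as richness grows,
#' interpolating log-linearly between the endpoints.
#'
#' @param kind `"fixed"` or `"variable"`.
#' @param t fixed threshold in (0, 1); ignored for variable schemes.
#' @param t_max,t_min variable-scheme endpoints: the threshold applied at
#'   richness `r_min` and at richness `r_max` respectively.
#' @param r_min,r_max richness range over which the variable threshold
#'   interpolates; richness outside the range is clamped.
#' @return an object of class `threshold_scheme`.
#' @export
threshold_scheme <- function(kind = c("fixed", "variable"), t = 0.01,
                             t_max = 0.1, t_min = 0.001,
                             r_min = 2, r_max = 21) {
  kind <- match.arg(kind)
  if (kind == "fixed" && (t <= 0 || t >= 1)) {
    stop("fixed threshold t must lie in (0, 1)", call. = FALSE)
  }
  if (t_min > t_max || t_min <= 0 || t_max >= 1) {
    stop("need 0 < t_min <= t_max < 1", call. = FALSE)
  }
  if (r_min >= r_max) stop("need r_min < r_max", call. = FALSE)
  structure(list(kind = kind, t = t, t_max = t_max, t_min = t_min,
                 r_min = r_min, r_max = r_max),
            class = "threshold_scheme")
}

#' @export
print.threshold_scheme <- function(x, ...) {
  if (x$kind == "fixed") {
    cat("Fixed read-frequency threshold: t =", x$t, "\n")
  } else {
    cat("Variable (allelic-richness) threshold:", x$t_max, "at richness",
        x$r_min, "down to", x$t_min, "at richness", x$r_max, "\n")
  }
  invisible(x)
}

#' Richness-dependent filtering threshold
#'
#' Log-linear interpolation between the scheme endpoints: a locus at
#' `r_min` alleles is filtered at `t_max` and a locus at `r_max` alleles
#' at `t_min`; intermediate richness maps onto intermediate thresholds on
#' the log scale (so the geometric midpoint of the endpoints sits at the
#' richness midpoint).
#'
#' @param richness per-locus allelic richness (number of distinct alleles
#'   in the reference population), integer >= 1; vectorised.
#' @param scheme a variable [threshold_scheme()].
#' @return the threshold(s) to apply, in (0, 1).
#' @export
variable_threshold <- function(richness, scheme) {
  stopifnot(inherits(scheme, "threshold_scheme"))
  if (scheme$kind != "variable") {
    stop("variable_threshold() needs a variable scheme", call. = FALSE)
  }
  frac <- (richness - scheme$r_min) / (scheme$r_max - scheme$r_min)
  frac <- pmin(pmax(frac, 0), 1)
  10^(log10(scheme$t_max) +
        (log10(scheme$t_min) - log10(scheme$t_max)) * frac)
}

#' Apply a threshold scheme to scaled counts
#'
#' Removes alleles whose within-(sample, locus) read frequency falls
#' below the applicable threshold: the fixed `t`, or the
#' richness-dependent [variable_threshold()] of the locus.
#'
#' @inheritParams low_freq_filter
#' @param scheme a [threshold_scheme()].
#' @param richness named integer vector (names = loci) of per-locus
#'   allelic richness; required for variable schemes.  Loci missing from
#'   it fall back to the observed number of alleles in `scaled`.
#' @return filtered scaled counts (not re-scaled).
#' @export
threshold_filter <- function(scaled, scheme, richness = NULL) {
  stopifnot(inherits(scheme, "threshold_scheme"))
  scaled <- as_scaled_counts(scaled)
  if (nrow(scaled) == 0L) return(scaled)
  if (scheme$kind == "fixed") {
    thr <- rep(scheme$t, nrow(scaled))
  } else {
    obs_rich <- tapply(scaled$allele, scaled$locus,
                       function(a) length(unique(a)))
    loci <- unique(scaled$locus)
    r <- obs_rich[loci]
    if (!is.null(richness)) {
      known <- loci %in% names(richness)
      r[known] <- richness[loci[known]]
    }
    names(r) <- loci
    thr <- variable_threshold(as.numeric(r[scaled$locus]), scheme)
  }
  key <- paste(scaled$sample, scaled$locus, sep = "\r")
  tot <- ave(scaled$scaled_reads, key, FUN = sum)
  out <- scaled[scaled$scaled_reads / tot >= thr, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Observed-allele mixture profile from filtered counts
#'
#' Reduces filtered scaled counts for one mixture to the per-locus set of
#' observed alleles, restricted to alleles present in the supplied
#' population frequencies (the mixture model can only evaluate alleles
#' whose population frequency is known).  The number of alleles dropped
#' by that restriction is recorded on the result.
#'
#' @param filtered scaled counts for a single mixture (one sample/unit).
#' @param pop population allele frequencies (`locus`, `allele`, `freq`),
#'   or NULL to keep every observed allele.
#' @param provenance label recorded on the profile, e.g. `"eDNA"` or
#'   `"tissue-pooled"`.
#' @return a mixture profile: data frame (`locus`, `allele`) with
#'   attributes `provenance` and `n_dropped_alleles`; loci with no
#'   surviving alleles are absent.
#' @export
to_mixture_profile <- function(filtered, pop = NULL, provenance = "eDNA") {
  filtered <- as_scaled_counts(filtered)
  if (length(unique(filtered$sample)) > 1L) {
    stop("a mixture profile describes one mixture; got ",
         length(unique(filtered$sample)), " samples", call. = FALSE)
  }
  prof <- unique(filtered[c("locus", "allele")])
  dropped <- 0L
  if (!is.null(pop)) {
    pop <- as_pop_freqs_df(pop)
    keep <- paste(prof$locus, prof$allele, sep = "\r") %in%
      paste(pop$locus, pop$allele, sep = "\r")
    dropped <- sum(!keep)
    prof <- prof[keep, , drop = FALSE]
  }
  prof <- prof[order(prof$locus, prof$allele), , drop = FALSE]
  rownames(prof) <- NULL
  attr(prof, "provenance") <- provenance
  attr(prof, "n_dropped_alleles") <- dropped
  prof
}

#' Full eDNA processing chain
#'
#' Composes the stages in their fixed order: minimum-read filter,
#' scaling to 100, per-sample low-frequency filter (optional), replicate
#' pooling, and the threshold scheme on the pooled counts.  The order is
#' deliberate: scaling before pooling weights replicates equally
#' regardless of their depths, and thresholds act on the pooled material
#' actually used for estimation.
#'
#' @inheritParams min_read_filter
#' @param replicate_map data frame (`sample`, `unit`); NULL treats every
#'   sample as its own unit.
#' @param scheme a [threshold_scheme()] applied to the pooled counts, or
#'   NULL for none.
#' @param low_freq per-sample low-frequency filter value, or NULL to skip
#'   the per-sample filter (e.g. when the scheme itself is the object of
#'   study).
#' @param richness per-locus richness for variable schemes.
#' @return pooled, filtered scaled counts (one pseudo-sample per unit).
#' @export
edna_pipeline <- function(counts, replicate_map = NULL, scheme = NULL,
                          min_reads = 10, low_freq = 0.01, richness = NULL) {
  counts <- min_read_filter(counts, min_reads)
  scaled <- scale_to_100(counts)
  if (!is.null(low_freq)) scaled <- low_freq_filter(scaled, low_freq)
  if (is.null(replicate_map)) {
    replicate_map <- data.frame(sample = unique(scaled$sample),
                                unit = unique(scaled$sample))
  }
  pooled <- pool_replicates(scaled, replicate_map)
  if (!is.null(scheme)) pooled <- threshold_filter(pooled, scheme, richness)
  pooled
}
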