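#' @title Microsatellite genotype calling and locus QC
#'
#' @description
#' Diploid genotypes are called from per-individual, per-locus allele
#' read counts with simple depth and fraction rules: the top allele by
#' read count is the first allele; the second-ranked allele is accepted
#' iff it carries at least `het_fraction` of the locus reads and at least
#' `min_depth` reads, otherwise the call is homozygous; loci whose top
#' allele falls below `min_depth` are missing.  Locus QC tests
#' Hardy-Weinberg proportions and flags heterozygote-excess loci (the
#' signature of co-amplified paralogues) for exclusion.
#' @name genotyping
NULL

#' Call one diploid genotype from allele read counts
#'
#' @param counts named numeric vector: allele identifier -> read count,
#'   for one individual at one locus.
#' @param min_depth minimum reads for any allele to be considered, and
#'   for the call not to be missing.
#' @param het_fraction minimum fraction of total locus reads on the
#'   second allele for a heterozygous call (boundary inclusive).
#' @return character vector of length 2 (`c(a1, a2)`, `a1` the top
#'   allele, equal for homozygotes) or `NULL` for a missing call.
#'   Read-count ties for the top allele are broken by allele identifier
#'   order.
#' @export
#' @examples
#' call_genotype(c(A = 80, B = 20))   # heterozygote A/B
#' call_genotype(c(A = 95, B = 5))    # homozygote A/A
call_genotype <- function(counts, min_depth = 10, het_fraction = 0.2) {
  if (length(counts) == 0L) return(NULL)
  if (any(counts < 0)) stop("read counts must be >= 0", call. = FALSE)
  ord <- order(-counts, names(counts))   # ties -> lexicographic allele id
  counts <- counts[ord]
  if (counts[1] < min_depth) return(NULL)
  total <- sum(counts)
  if (length(counts) >= 2L &&
      counts[2] >= het_fraction * total && counts[2] >= min_depth) {
    return(c(names(counts)[1], names(counts)[2]))
  }
  c(names(counts)[1], names(counts)[1])
}

#' Genotype every individual at every locus
#'
#' Applies [call_genotype()] across a tissue read count table (with
#' `sample` interpreted as the individual) and reports per-individual
#' missingness.  Individuals lacking counts at a panel locus receive a
#' missing call; the output is invariant to row order of the input.
#'
#' @param counts read count table (`sample`, `locus`, `allele`, `reads`)
#'   of tissue samples.
#' @param panel_loci character vector of loci to call; defaults to the
#'   loci present in `counts`.
#' @inheritParams call_genotype
#' @return list with `genotypes` (data frame `individual`, `locus`,
#'   `allele1`, `allele2`, NA for missing) and `missingness` (data frame
#'   `individual`, `n_missing`).
#' @export
genotype_matrix <- function(counts, panel_loci = NULL, min_depth = 10,
                            het_fraction = 0.2) {
  counts <- as_read_count_table(counts)
  individuals <- sort(unique(counts$sample))
  if (is.null(panel_loci)) panel_loci <- sort(unique(counts$locus))
  grid <- expand.grid(individual = individuals, locus = panel_loci,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key_counts <- split(seq_len(nrow(counts)),
                      paste(counts$sample, counts$locus, sep = "\r"))
  calls <- lapply(seq_len(nrow(grid)), function(i) {
    rows <- key_counts[[paste(grid$individual[i], grid$locus[i],
                              sep = "\r")]]
    if (is.null(rows)) return(c(NA_character_, NA_character_))
    v <- counts$reads[rows]
    names(v) <- counts$allele[rows]
    g <- call_genotype(v, min_depth, het_fraction)
    if (is.null(g)) c(NA_character_, NA_character_) else g
  })
  calls <- do.call(rbind, calls)
  genotypes <- data.frame(individual = grid$individual, locus = grid$locus,
                          allele1 = calls[, 1], allele2 = calls[, 2],
                          stringsAsFactors = FALSE)
  genotypes <- genotypes[order(genotypes$individual, genotypes$locus), ]
  rownames(genotypes) <- NULL
  miss <- tapply(is.na(genotypes$allele1), genotypes$individual, sum)
  missingness <- data.frame(individual = names(miss),
                            n_missing = as.integer(miss),
                            stringsAsFactors = FALSE)
  rownames(missingness) <- NULL
  list(genotypes = genotypes, missingness = missingness)
}

as_genotypes_df <- function(genotypes) {
  genotypes <- as.data.frame(genotypes)
  need <- c("individual", "locus", "allele1", "allele2")
  if (!all(need %in% names(genotypes))) {
    stop("genotypes need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  for (col in need) genotypes[[col]] <- as.character(genotypes[[col]])
  genotypes
}

#' Hardy-Weinberg goodness-of-fit test for one locus
#'
#' Chi-square goodness of fit of observed genotype counts against
#' Hardy-Weinberg expectations computed from the sample allele
#' frequencies (expected counts \eqn{N p_i^2} and \eqn{2 N p_i p_j};
#' degrees of freedom = number of genotype classes minus number of
#' alleles).  A Monte-Carlo p-value, obtained by permuting gene copies
#' among individuals, is available for sparse multiallelic tables where
#' the asymptotic reference is unreliable.  A locus is flagged for
#' exclusion only when the deviation is significant *and* heterozygotes
#' are in excess; a heterozygote deficit (the allelic-dropout signature)
#' is reported but not auto-excluded.
#'
#' @param genotypes data frame (`individual`, `locus`, `allele1`,
#'   `allele2`) holding calls for a single locus; missing calls are
#'   ignored.
#' @param alpha significance level for the exclusion flag.
#' @param method `"chisq"` for the asymptotic p-value or `"permutation"`
#'   for the Monte-Carlo p-value.
#' @param n_perm number of permutations for the Monte-Carlo p-value.
#' @return one-row data frame: `locus`, `n`, `hwe_statistic`, `hwe_p`,
#'   `het_observed`, `het_expected`, `excluded`, `reason`.
#' @export
hwe_test <- function(genotypes, alpha = 0.05,
                     method = c("chisq", "permutation"), n_perm = 999) {
  method <- match.arg(method)
  genotypes <- as_genotypes_df(genotypes)
  locus <- unique(genotypes$locus)
  if (length(locus) != 1L) {
    stop("hwe_test() expects genotypes from a single locus", call. = FALSE)
  }
  g <- genotypes[!is.na(genotypes$allele1) & !is.na(genotypes$allele2), ,
                 drop = FALSE]
  n <- nrow(g)
  empty <- data.frame(locus = locus, n = n, hwe_statistic = NA_real_,
                      hwe_p = NA_real_, het_observed = NA_real_,
                      het_expected = NA_real_, excluded = FALSE,
                      reason = "", stringsAsFactors = FALSE)
  if (n < 5L) {
    empty$reason <- "test skipped: fewer than 5 individuals"
    return(empty)
  }
  alleles <- sort(unique(c(g$allele1, g$allele2)))
  if (length(alleles) < 2L) {
    empty$het_observed <- 0
    empty$het_expected <- 0
    empty$reason <- "test skipped: monomorphic"
    return(empty)
  }
  stat_fun <- function(a1, a2) {
    copies <- c(a1, a2)
    p <- prop.table(table(factor(copies, levels = alleles)))
    k <- length(alleles)
    geno <- paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
    pairs <- outer(alleles, alleles, function(x, y) paste(pmin(x, y),
                                                          pmax(x, y),
                                                          sep = "/"))
    classes <- unique(pairs[upper.tri(pairs, diag = TRUE)])
    obs <- table(factor(geno, levels = classes))
    pm <- outer(as.numeric(p), as.numeric(p))
    exp_mat <- pm + t(pm) - diag(diag(pm))   # p_i^2 diag, 2 p_i p_j off
    dimnames(exp_mat) <- list(alleles, alleles)
    expc <- vapply(strsplit(classes, "/", fixed = TRUE),
                   function(ab) exp_mat[ab[1], ab[2]], numeric(1)) * length(a1)
    stat <- sum((as.numeric(obs) - expc)^2 / expc)
    list(stat = stat, df = length(classes) - k,
         het_obs = mean(a1 != a2), het_exp = 1 - sum(p^2))
  }
  obs <- stat_fun(g$allele1, g$allele2)
  if (method == "chisq") {
    p_val <- stats::pchisq(obs$stat, obs$df, lower.tail = FALSE)
  } else {
    copies <- c(g$allele1, g$allele2)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      perm <- sample(copies)
      s <- stat_fun(perm[seq_len(n)], perm[n + seq_len(n)])$stat
      if (s >= obs$stat - 1e-12) hits <- hits + 1L
    }
    p_val <- (1 + hits) / (1 + n_perm)
  }
  excess <- obs$het_obs > obs$het_exp
  excluded <- is.finite(p_val) && p_val < alpha && excess
  reason <- if (excluded) {
    "significant HWE deviation with heterozygote excess"
  } else if (is.finite(p_val) && p_val < alpha && !excess) {
    "HWE deviation with heterozygote deficit (reported, not excluded)"
  } else ""
  data.frame(locus = locus, n = n, hwe_statistic = obs$stat, hwe_p = p_val,
             het_observed = obs$het_obs, het_expected = obs$het_exp,
             excluded = excluded, reason = reason, stringsAsFactors = FALSE)
}

#' Locus QC over a full genotype table
#'
#' Runs [hwe_test()] on every locus and returns the combined QC report.
#'
#' @inheritParams hwe_test
#' @param genotypes genotype data frame covering any number of loci.
#' @return data frame with one [hwe_test()] row per locus.
#' @export
locus_qc <- function(genotypes, alpha = 0.05,
                     method = c("chisq", "permutation"), n_perm = 999) {
  genotypes <- as_genotypes_df(genotypes)
  out <- lapply(split(genotypes, genotypes$locus), hwe_test, alpha = alpha,
                method = method, n_perm = n_perm)
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Population allele frequencies from genotypes
#'
#' Counts allele copies over the 2N gene copies of the non-missing calls
#' at each locus and normalises to frequencies.
#'
#' @param genotypes genotype data frame (`individual`, `locus`,
#'   `allele1`, `allele2`).
#' @return data frame (`locus`, `allele`, `freq`) with per-locus
#'   frequencies summing to 1.
#' @export
#' @examples
#' g <- data.frame(individual = c("i1", "i2"), locus = "L1",
#'                 allele1 = c("A", "A"), allele2 = c("A", "B"))
#' pop_allele_freqs(g)   # A: 0.75, B: 0.25
pop_allele_freqs <- function(genotypes) {
  genotypes <- as_genotypes_df(genotypes)
  g <- genotypes[!is.na(genotypes$allele1) & !is.na(genotypes$allele2), ,
                 drop = FALSE]
  if (nrow(g) == 0L) {
    stop("no non-missing genotype calls", call. = FALSE)
  }
  copies <- data.frame(locus = c(g$locus, g$locus),
                       allele = c(g$allele1, g$allele2),
                       stringsAsFactors = FALSE)
  agg <- aggregate(cbind(count = rep(1L, nrow(copies))) ~ locus + allele,
                   data = copies, FUN = sum)
  tot <- ave(agg$count, agg$locus, FUN = sum)
  out <- data.frame(locus = agg$locus, allele = agg$allele,
                    freq = agg$count / tot, stringsAsFactors = FALSE)
  out <- out[order(out$locus, out$allele), ]
  rownames(out) <- NULL
  out
}

#' Pooled observed-allele profile from member genotypes
#'
#' The union of the member individuals' called alleles per locus: the
#' mixture profile a perfectly detected pooled-tissue sample would show.
#'
#' @param genotypes genotype data frame for the member individuals.
#' @param pop optional population frequencies used to restrict the
#'   profile as in [to_mixture_profile()].
#' @return a mixture profile data frame (`locus`, `allele`) with
#'   provenance `"tissue-pooled"`.
#' @export
genotypes_to_profile <- function(genotypes, pop = NULL) {
  genotypes <- as_genotypes_df(genotypes)
  g <- genotypes[!is.na(genotypes$allele1), , drop = FALSE]
  prof <- unique(data.frame(locus = c(g$locus, g$locus),
                            allele = c(g$allele1, g$allele2),
                            stringsAsFactors = FALSE))
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
  attr(prof, "provenance") <- "tissue-pooled"
  attr(prof, "n_dropped_alleles") <- dropped
  prof
}
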