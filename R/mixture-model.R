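#' @title DNA-mixture contributor likelihood
#'
#' @description
#' The masked-allele model gives the probability that `x` diploid
#' contributors, drawn from a population with allele frequencies `p`,
#' jointly display exactly the observed set of `n` distinct alleles at one
#' locus.  The `2x` gene copies in the mixture are treated as independent
#' draws from the population frequencies; `d = 2x - n` copies are "masked"
#' (hidden behind an already-observed allele).  Summing the multinomial
#' probability over every way of allocating the masked copies gives the
#' locus likelihood, and the product over loci yields a maximum-likelihood
#' estimate of the number of contributors.
#'
#' Three numerically equivalent evaluators are provided:
#' \itemize{
#'   \item [likelihood_bruteforce()] enumerates the allele-copy
#'     compositions directly (reference implementation, small problems);
#'   \item [likelihood_efficient()] uses the inclusion-exclusion identity
#'     over allele subsets with compensated (Kahan) summation;
#'   \item [likelihood_grid()] evaluates the whole candidate grid at once
#'     by binomial convolution of the per-allele generating functions,
#'     which is cancellation-free and is what [estimate_contributors()]
#'     uses internally.
#' }
#' @name mixture_likelihood
NULL

check_freqs <- function(freqs, sum_tol = 1e-9) {
  if (length(freqs) < 1L) {
    stop("at least one allele frequency is required", call. = FALSE)
  }
  if (any(!is.finite(freqs)) || any(freqs <= 0)) {
    stop("invalid allele frequency: all frequencies must be finite and > 0",
         call. = FALSE)
  }
  if (any(freqs > 1)) {
    stop("invalid allele frequency: frequencies must be <= 1", call. = FALSE)
  }
  if (sum(freqs) > 1 + sum_tol) {
    stop("invalid allele frequencies: sum exceeds 1 (", format(sum(freqs)),
         ")", call. = FALSE)
  }
  invisible(freqs)
}

check_x <- function(x) {
  if (length(x) != 1L || !is.finite(x) || x < 1 || x != floor(x)) {
    stop("x must be a single positive integer", call. = FALSE)
  }
  invisible(as.integer(x))
}

#' Composition-sum mixture likelihood (reference form)
#'
#' Enumerates every composition of the `2x` gene copies into `n` positive
#' parts (one per observed allele) and sums the multinomial probabilities.
#' Exponential in problem size; intended as the reference oracle for the
#' efficient forms on small problems.
#'
#' @param freqs numeric vector of population frequencies of the observed
#'   alleles, each in (0, 1], summing to at most 1.
#' @param x proposed number of diploid contributors (positive integer).
#' @param max_compositions enumeration cap; the number of compositions is
#'   `choose(2x - 1, n - 1)` and exceeding the cap raises an error
#'   suggesting the efficient form.
#' @return the likelihood, a probability in \[0, 1\]; exactly 0 when
#'   `2x < n` (fewer gene copies than distinct alleles).
#' @seealso [likelihood_efficient()], [likelihood_grid()]
#' @export
#' @examples
#' likelihood_bruteforce(c(0.3, 0.7), x = 2)  # 1 - 0.3^4 - 0.7^4
likelihood_bruteforce <- function(freqs, x, max_compositions = 2e5) {
  check_freqs(freqs)
  x <- check_x(x)
  n <- length(freqs)
  m <- 2L * x
  if (m < n) return(0)
  n_comp <- choose(m - 1, n - 1)
  if (n_comp > max_composition_cap(max_compositions)) {
    stop("composition enumeration too large (", format(n_comp),
         " compositions); use the efficient form", call. = FALSE)
  }
  g <- compositions_positive(m, n)        # n_comp x n matrix, rows sum to m
  logp <- matrix(log(freqs), nrow(g), n, byrow = TRUE)
  log_terms <- lfactorial(m) - rowSums(lfactorial(g)) + rowSums(g * logp)
  sum(exp(log_terms))
}

max_composition_cap <- function(cap) {
  if (!is.finite(cap) || cap < 1) stop("invalid composition cap", call. = FALSE)
  cap
}

# All compositions of m into n positive integer parts, as a matrix.
compositions_positive <- function(m, n) {
  if (n == 1L) return(matrix(m, 1L, 1L))
  out <- vector("list", m - n + 1L)
  for (first in seq_len(m - n + 1L)) {
    rest <- compositions_positive(m - first, n - 1L)
    out[[first]] <- cbind(first, rest, deparse.level = 0)
  }
  do.call(rbind, out)
}

#' Inclusion-exclusion mixture likelihood
#'
#' Evaluates the same probability as [likelihood_bruteforce()] through the
#' subset identity: the probability that `2x` draws land in the observed
#' allele set with every allele represented equals
#' \eqn{\sum_{B \subseteq A} (-1)^{|A|-|B|} (\sum_{a \in B} p_a)^{2x}}.
#' The alternating series is accumulated with compensated (Kahan)
#' summation; residual cancellation slightly outside \[0, 1\] is clipped
#' when within `tol`, and an error is raised beyond it.
#'
#' @inheritParams likelihood_bruteforce
#' @param max_alleles subset-enumeration limit on the number of observed
#'   alleles (2^n subsets are visited).
#' @param tol numerical tolerance for clipping to \[0, 1\].
#' @param locus optional locus label used in error messages.
#' @return the likelihood, a probability in \[0, 1\].
#' @export
#' @examples
#' likelihood_efficient(c(0.2, 0.3, 0.5), x = 3)
likelihood_efficient <- function(freqs, x, max_alleles = 25L, tol = 1e-9,
                                 locus = NULL) {
  check_freqs(freqs)
  x <- check_x(x)
  n <- length(freqs)
  if (n > max_alleles) {
    stop("too many alleles (", n, ") for subset enumeration; limit is ",
         max_alleles, call. = FALSE)
  }
  m <- 2L * x
  if (m < n) return(0)
  # subset sums and parities, built incrementally
  s <- 0
  size <- 0L
  for (p in freqs) {
    s <- c(s, s + p)
    size <- c(size, size + 1L)
  }
  terms <- ifelse((n - size) %% 2L == 0L, 1, -1) * s^m
  total <- kahan_sum(terms)
  if (total < -tol || total > 1 + tol) {
    where <- if (is.null(locus)) "" else paste0(" at locus ", locus)
    stop("numerical instability in inclusion-exclusion likelihood", where,
         " for x = ", x, " (value ", format(total), ")", call. = FALSE)
  }
  min(max(total, 0), 1)
}

# Compensated (Kahan) summation of a numeric vector.
kahan_sum <- function(v) {
  total <- 0
  comp <- 0
  for (val in v) {
    y <- val - comp
    t <- total + y
    comp <- (t - total) - y
    total <- t
  }
  total
}

#' Mixture likelihood over a grid of contributor counts
#'
#' Cancellation-free evaluation of the masked-allele likelihood for every
#' even copy number up to `2 * max(x_grid)` at once.  Writing the
#' likelihood as \eqn{m! [z^m] \prod_i (e^{p_i z} - 1)} with `m = 2x`, the
#' factorial-scaled coefficients are probabilities in \[0, 1\] and are
#' accumulated by binomial convolution, one allele at a time, so no
#' subtraction ever occurs.  Frequencies are internally renormalised to
#' sum to one and the factor `(sum p)^m` is restored in log space, which
#' keeps small-total allele sets representable.
#'
#' @inheritParams likelihood_bruteforce
#' @param x_grid ascending positive integer vector of candidate
#'   contributor counts.
#' @return numeric vector of log-likelihoods, one per element of
#'   `x_grid`; `-Inf` where `2x < n`.
#' @export
likelihood_grid <- function(freqs, x_grid) {
  check_freqs(freqs)
  if (length(x_grid) < 1L || any(x_grid < 1) || any(x_grid != floor(x_grid)) ||
      is.unsorted(x_grid, strictly = TRUE)) {
    stop("x_grid must be a strictly ascending vector of positive integers",
         call. = FALSE)
  }
  n <- length(freqs)
  m_max <- 2L * max(x_grid)
  if (m_max < n) return(rep(-Inf, length(x_grid)))
  ptot <- sum(freqs)
  q <- freqs / ptot
  # cov[m] = P(m iid draws from q cover all alleles folded in so far);
  # exact 0 while m is below that count.  All convolution terms are
  # nonnegative, so there is no cancellation at any stage.
  tabs <- convolution_tables(m_max)
  cov <- q[1]^seq_len(m_max)
  if (n > 1L) {
    for (i in 2:n) {
      v <- c(0, q[i]^seq_len(m_max))
      cov <- as.numeric((tabs$choose * matrix(v[tabs$shift], m_max)) %*% cov)
      cov[seq_len(min(i - 1L, m_max))] <- 0
    }
  }
  m_grid <- 2L * x_grid
  out <- rep(-Inf, length(x_grid))
  ok <- m_grid >= n & cov[m_grid] > 0
  out[ok] <- log(cov[m_grid[ok]]) + m_grid[ok] * log(ptot)
  out
}

# cached binomial-convolution tables: choose(m, j) and an index matrix
# mapping (m, j) to the power m - j (0 marks j >= m, i.e. no term)
convolution_tables <- local({
  cache <- NULL
  function(m_max) {
    if (is.null(cache) || nrow(cache$choose) < m_max) {
      m <- seq_len(m_max)
      cache <<- list(
        choose = outer(m, m, choose),
        shift = pmax(outer(m, m, "-"), 0L) + 1L)
    } else if (nrow(cache$choose) > m_max) {
      m <- seq_len(m_max)
      return(list(choose = cache$choose[m, m, drop = FALSE],
                  shift = pmax(outer(m, m, "-"), 0L) + 1L))
    }
    cache
  }
})

#' Multi-locus log-likelihood profile for the contributor count
#'
#' Sums per-locus log-likelihoods of an observed mixture profile over a
#' grid of candidate diploid contributor counts.  Observed alleles with no
#' entry in the population frequencies are dropped before evaluation (the
#' model can only consider alleles with known population frequencies);
#' loci whose observed set becomes empty are skipped.  Both events are
#' counted on the result.
#'
#' @param profile a mixture profile: data frame with columns `locus` and
#'   `allele` listing the distinct alleles observed at each locus (see
#'   [to_mixture_profile()]).
#' @param pop population allele frequencies: data frame with columns
#'   `locus`, `allele`, `freq` (per-locus frequencies summing to 1).
#' @param x_grid ascending positive integer candidate contributor counts;
#'   the default 1..100 spans the study designs this model targets and can
#'   be raised for larger mixtures.
#' @return an object of class `contributor_estimate` without the `x_hat`
#'   selection: list with `x_grid`, `loglik`, `n_informative_loci`,
#'   `n_dropped_alleles`, `n_skipped_loci`.
#' @export
loglik_profile <- function(profile, pop, x_grid = 1:100) {
  profile <- as_mixture_profile_df(profile)
  pop <- as_pop_freqs_df(pop)
  if (length(x_grid) < 1L) stop("x_grid must be nonempty", call. = FALSE)
  loci <- unique(profile$locus)
  loglik <- numeric(length(x_grid))
  n_informative <- 0L
  n_dropped <- 0L
  n_skipped <- 0L
  for (loc in loci) {
    obs <- unique(profile$allele[profile$locus == loc])
    popl <- pop[pop$locus == loc, , drop = FALSE]
    keep <- obs %in% popl$allele
    n_dropped <- n_dropped + sum(!keep)
    obs <- obs[keep]
    if (length(obs) == 0L) {
      n_skipped <- n_skipped + 1L
      next
    }
    p <- popl$freq[match(obs, popl$allele)]
    ll <- likelihood_grid(p, x_grid)
    if (all(!is.finite(ll))) {
      stop("locus ", loc, " has likelihood 0 at every candidate x (",
           length(obs), " observed alleles need x >= ",
           ceiling(length(obs) / 2),
           "); raise the x_grid upper bound", call. = FALSE)
    }
    loglik <- loglik + ll
    n_informative <- n_informative + 1L
  }
  if (n_informative == 0L) {
    stop("no informative loci: estimation impossible", call. = FALSE)
  }
  structure(
    list(x_grid = as.integer(x_grid), loglik = loglik,
         x_hat = NA_integer_, boundary = NA,
         n_informative_loci = n_informative,
         n_dropped_alleles = n_dropped, n_skipped_loci = n_skipped,
         bias = NA_real_),
    class = "contributor_estimate")
}

#' Maximum-likelihood number of mixture contributors
#'
#' Selects the candidate contributor count maximising the multi-locus
#' log-likelihood of [loglik_profile()].  Ties are broken toward the
#' smallest x (the most parsimonious abundance claim).  An estimate at the
#' upper grid boundary is flagged, since the true maximiser may lie beyond
#' the grid.
#'
#' @inheritParams loglik_profile
#' @param true_x optional known true contributor count; when supplied the
#'   result carries `bias = x_hat - true_x`.
#' @return a `contributor_estimate`: list with `x_grid`, `loglik`,
#'   `x_hat`, `boundary` flag, locus/allele accounting, and `bias`.
#' @export
#' @examples
#' pop <- data.frame(locus = "L1", allele = c("a", "b", "c"),
#'                   freq = c(0.5, 0.3, 0.2))
#' prof <- data.frame(locus = "L1", allele = c("a", "b"))
#' est <- estimate_contributors(prof, pop, x_grid = 1:20)
#' est$x_hat
estimate_contributors <- function(profile, pop, x_grid = 1:100,
                                  true_x = NULL) {
  est <- loglik_profile(profile, pop, x_grid)
  best <- which.max(est$loglik)   # which.max returns the first (smallest x) tie
  est$x_hat <- est$x_grid[best]
  est$boundary <- best == length(est$x_grid)
  if (est$boundary) {
    warning("contributor estimate lies at the x_grid upper boundary (",
            est$x_hat, "); the maximiser may exceed the grid", call. = FALSE)
  }
  if (!is.null(true_x)) est$bias <- est$x_hat - true_x
  est
}

#' @export
print.contributor_estimate <- function(x, ...) {
  cat("Contributor estimate (masked-allele DNA mixture model)\n")
  if (!is.na(x$x_hat)) {
    cat("  x_hat:", x$x_hat,
        if (isTRUE(x$boundary)) "(at grid boundary)" else "", "\n")
  }
  cat("  grid:", min(x$x_grid), "..", max(x$x_grid), "\n")
  cat("  informative loci:", x$n_informative_loci,
      "| skipped loci:", x$n_skipped_loci,
      "| dropped alleles:", x$n_dropped_alleles, "\n")
  if (!is.na(x$bias)) cat("  bias (x_hat - truth):", x$bias, "\n")
  invisible(x)
}

as_mixture_profile_df <- function(profile) {
  profile <- as.data.frame(profile)
  if (!all(c("locus", "allele") %in% names(profile))) {
    stop("a mixture profile needs columns 'locus' and 'allele'",
         call. = FALSE)
  }
  profile$locus <- as.character(profile$locus)
  profile$allele <- as.character(profile$allele)
  profile
}

as_pop_freqs_df <- function(pop, tol = 1e-6) {
  pop <- as.data.frame(pop)
  if (!all(c("locus", "allele", "freq") %in% names(pop))) {
    stop("population frequencies need columns 'locus', 'allele', 'freq'",
         call. = FALSE)
  }
  pop$locus <- as.character(pop$locus)
  pop$allele <- as.character(pop$allele)
  if (any(pop$freq <= 0)) {
    stop("population frequencies must be > 0", call. = FALSE)
  }
  sums <- tapply(pop$freq, pop$locus, sum)
  if (any(abs(sums - 1) > tol)) {
    bad <- names(sums)[abs(sums - 1) > tol][1]
    stop("population frequencies at locus ", bad, " sum to ",
         format(sums[[bad]]), ", not 1", call. = FALSE)
  }
  pop
}
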