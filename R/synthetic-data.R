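#' @title Ground-truthed simulation of the mesocosm and field study designs
#'
#' @description
#' Generates inputs with the statistical structure the analysis assumes:
#' a panel of tetranucleotide microsatellite loci with known allele
#' sequences; a single panmictic population with Dirichlet-distributed
#' allele frequencies and Hardy-Weinberg genotypes; mesocosms stocked at
#' densities 1/3/5/10 in triplicate (one 11-fish unit); tissue and eDNA
#' read counts with unequal per-individual DNA contributions, PCR
#' stutter, sequencing substitution errors and allelic dropout; and
#' optional paired-end FASTQ for end-to-end read-processing tests.
#' Every generator is a pure function of its inputs and seed.
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' Defaults describe the emulated study: 28 multiallelic loci with 2-21
#' alleles per locus (mean ~9.4), 58 mesocosm fish plus 15 field fish
#' from one panmictic population, mesocosm densities 1/3/5/10 in
#' triplicate with one 11-fish unit, duplicate eDNA water samples per
#' mesocosm and triplicate field samples, and total read depths of about
#' 45,000 per tissue sample, 37,000 per mesocosm eDNA sample and 4,300
#' per field eDNA sample.
#'
#' @param n_loci number of panel loci.
#' @param richness_min,richness_max,richness_mean per-locus allele count
#'   range and target mean; counts are drawn as
#'   `richness_min + Binomial(richness_max - richness_min, p)` with `p`
#'   matching the mean.
#' @param n_individuals genotyped individuals (mesocosm + field tissue).
#' @param freq_concentration symmetric Dirichlet concentration for
#'   population allele frequencies.
#' @param mesocosm_sizes fish per mesocosm unit.
#' @param edna_replicates replicate water samples per mesocosm.
#' @param field_replicates replicate water samples in the field trial.
#' @param field_contributors true number of individuals shedding DNA
#'   into the field samples.
#' @param tissue_depth,edna_depth,field_depth target total reads per
#'   sample; per-locus depths are negative-binomial around
#'   `depth / n_loci` with dispersion `depth_dispersion`.
#' @param depth_dispersion negative-binomial size parameter for
#'   per-locus depth.
#' @param weight_concentration symmetric Dirichlet concentration for
#'   per-individual DNA contribution weights (lower = more unequal).
#' @param amp_bias_shape Beta(`shape`, `shape`) allele amplification
#'   bias for heterozygotes (larger = closer to 50/50).
#' @param stutter_rate probability a read stutters to one repeat unit
#'   shorter than its template allele.
#' @param sub_rate probability a read carries a substitution error,
#'   producing an erroneous sequence variant.
#' @param dropout_rate baseline per-allele dropout probability in eDNA
#'   samples, inflated for low-contribution alleles.
#' @param repeat_min repeat count of the shortest allele at a locus;
#'   allele repeat counts are contiguous from it, so single-repeat
#'   stutter usually lands on a real neighbouring allele.
#' @param read_len sequencing read length for FASTQ emission.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_loci = 28L, richness_min = 2L, richness_max = 21L,
                       richness_mean = 9.4, n_individuals = 73L,
                       freq_concentration = 1,
                       mesocosm_sizes = c(1, 1, 1, 3, 3, 3, 5, 5, 5,
                                          10, 10, 11),
                       edna_replicates = 2L, field_replicates = 3L,
                       field_contributors = 10L,
                       tissue_depth = 45000, edna_depth = 37000,
                       field_depth = 4300, depth_dispersion = 5,
                       weight_concentration = 1, amp_bias_shape = 50,
                       stutter_rate = 0.05, sub_rate = 0.005,
                       dropout_rate = 0.02, repeat_min = 10L,
                       read_len = 250L) {
  rates <- c(stutter_rate, sub_rate, dropout_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("error rates must lie in [0, 1]", call. = FALSE)
  }
  if (any(c(tissue_depth, edna_depth, field_depth) <= 0)) {
    stop("depths must be positive", call. = FALSE)
  }
  structure(as.list(environment()), class = "sim_config")
}

maybe_with_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

rdirichlet1 <- function(k, conc) {
  repeat {
    g <- stats::rgamma(k, shape = conc)
    if (all(g > 0) && sum(g) > 0) return(g / sum(g))
  }
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a microsatellite locus panel
#'
#' Loci carry distinct random forward/reverse primers (equal length, so
#' mutually non-prefixing), a random non-homopolymer tetranucleotide
#' motif, and an allele universe of contiguous repeat counts starting at
#' `repeat_min`.  Allele sequences are
#' primer + flank + motif repeats + flank, so all alleles of a locus
#' share their first 40 bases, which form the reference prefix.
#'
#' @param config a [sim_config()].
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return a `locus_panel`: list with `loci` (locus, fwd_primer,
#'   rev_primer, reference_prefix, motif, flank1, flank2, richness) and
#'   `alleles` (locus, allele, repeats, sequence).
#' @export
gen_panel <- function(config = sim_config(), seed = NULL) {
  maybe_with_seed(seed, {
    n <- config$n_loci
    locus <- sprintf("L%02d", seq_len(n))
    repeat {
      fwd <- vapply(seq_len(n), function(i) random_dna(20L), character(1))
      rev <- vapply(seq_len(n), function(i) random_dna(20L), character(1))
      if (!anyDuplicated(c(fwd, rev))) break
    }
    motif <- vapply(seq_len(n), function(i) {
      repeat {
        m <- random_dna(4L)
        if (length(unique(strsplit(m, "")[[1]])) > 1L) return(m)
      }
    }, character(1))
    flank1 <- vapply(seq_len(n), function(i) random_dna(20L), character(1))
    flank2 <- vapply(seq_len(n), function(i) random_dna(26L), character(1))
    span <- config$richness_max - config$richness_min
    richness <- config$richness_min +
      stats::rbinom(n, span, (config$richness_mean - config$richness_min) /
                      span)
    loci <- data.frame(locus = locus, fwd_primer = fwd, rev_primer = rev,
                       reference_prefix = paste0(fwd, flank1),
                       motif = motif, flank1 = flank1, flank2 = flank2,
                       richness = richness, stringsAsFactors = FALSE)
    alleles <- do.call(rbind, lapply(seq_len(n), function(i) {
      reps <- config$repeat_min + seq_len(richness[i]) - 1L
      data.frame(locus = locus[i], allele = as.character(reps),
                 repeats = reps,
                 sequence = vapply(reps, function(k) {
                   allele_sequence_row(loci[i, ], as.character(k))
                 }, character(1)),
                 stringsAsFactors = FALSE)
    }))
    structure(list(loci = loci, alleles = alleles), class = "locus_panel")
  })
}

# Deterministic allele id -> sequence.  Plain ids are repeat counts;
# "<k>_e<j>" is the substitution-error variant of allele k with the j-th
# base of the trailing flank advanced by one (A->C->G->T->A).
allele_sequence_row <- function(locus_row, allele_id) {
  parts <- strsplit(allele_id, "_e", fixed = TRUE)[[1]]
  k <- as.integer(parts[1])
  flank2 <- locus_row$flank2
  if (length(parts) == 2L) {
    j <- as.integer(parts[2])
    base <- substr(flank2, j, j)
    nxt <- c(A = "C", C = "G", G = "T", T = "A")[[base]]
    substr(flank2, j, j) <- nxt
  }
  paste0(locus_row$fwd_primer, locus_row$flank1,
         strrep(locus_row$motif, k), flank2,
         revcomp_chr(locus_row$rev_primer))
}

#' Sequence of any allele identifier at a panel locus
#'
#' @param panel a `locus_panel`.
#' @param locus locus identifier.
#' @param allele allele identifier: a repeat count, optionally with an
#'   `_e<j>` substitution-variant suffix.
#' @return the amplicon sequence (character string).
#' @export
allele_sequence <- function(panel, locus, allele) {
  loci <- panel_loci_df(panel)
  row <- loci[loci$locus == locus, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown locus ", locus, call. = FALSE)
  allele_sequence_row(row, allele)
}

#' Generate population allele frequencies and diploid genotypes
#'
#' Per-locus frequencies are symmetric-Dirichlet draws over the panel's
#' allele universe; genotypes are two independent gene copies per locus
#' per individual (Hardy-Weinberg, one panmictic population).
#'
#' @inheritParams gen_panel
#' @param panel a `locus_panel` from [gen_panel()].
#' @param n_individuals number of diploid individuals to genotype;
#'   defaults to `config$n_individuals`.
#' @param freqs optional pre-existing population frequencies (`locus`,
#'   `allele`, `freq`); when supplied, only genotypes are drawn (further
#'   individuals from the same population).
#' @return list with `freqs` (locus, allele, freq) and `genotypes`
#'   (individual, locus, allele1, allele2).
#' @export
gen_population <- function(panel, config = sim_config(),
                           n_individuals = config$n_individuals,
                           freqs = NULL, seed = NULL) {
  maybe_with_seed(seed, {
    alleles <- split(panel$alleles$allele, panel$alleles$locus)
    if (is.null(freqs)) {
      freqs <- do.call(rbind, lapply(names(alleles), function(loc) {
        a <- alleles[[loc]]
        data.frame(locus = loc, allele = a,
                   freq = rdirichlet1(length(a), config$freq_concentration),
                   stringsAsFactors = FALSE)
      }))
    }
    ids <- sprintf("i%03d", seq_len(n_individuals))
    genotypes <- do.call(rbind, lapply(names(alleles), function(loc) {
      f <- freqs[freqs$locus == loc, ]
      a1 <- sample(f$allele, n_individuals, replace = TRUE, prob = f$freq)
      a2 <- sample(f$allele, n_individuals, replace = TRUE, prob = f$freq)
      data.frame(individual = ids, locus = loc, allele1 = a1, allele2 = a2,
                 stringsAsFactors = FALSE)
    }))
    genotypes <- genotypes[order(genotypes$individual, genotypes$locus), ]
    rownames(genotypes) <- NULL
    list(freqs = freqs, genotypes = genotypes)
  })
}

#' Assign individuals to mesocosm units
#'
#' Shuffles individuals into disjoint units of the configured sizes
#' (default 3x1, 3x3, 3x5, 2x10 and one 11-fish unit, 58 fish in all).
#' Units are labelled by density and replicate letter, e.g. `"5b"`.
#'
#' @inheritParams gen_population
#' @param genotypes genotype data frame; its individuals are assigned.
#' @return data frame (`unit`, `individual`); disjoint membership.
#' @export
gen_mesocosms <- function(genotypes, config = sim_config(), seed = NULL) {
  maybe_with_seed(seed, {
    sizes <- config$mesocosm_sizes
    ids <- sort(unique(genotypes$individual))
    if (length(ids) < sum(sizes)) {
      stop("need at least ", sum(sizes), " individuals for the mesocosm ",
           "design; got ", length(ids), call. = FALSE)
    }
    # replicate letters within each density; the 11-fish unit is the third
    # replicate of the 10-fish density
    density <- ifelse(sizes == 11, 10, sizes)
    rep_letter <- character(length(sizes))
    for (d in unique(density)) {
      idx <- which(density == d)
      rep_letter[idx] <- letters[seq_along(idx)]
    }
    unit <- paste0(density, rep_letter)
    chosen <- sample(ids, sum(sizes))
    data.frame(unit = rep(unit, sizes), individual = chosen,
               stringsAsFactors = FALSE)
  })
}

# stutter + substitution errors on one locus's counts
# counts: data.frame(allele, reads); allele ids are repeat counts (or
# error variants, which neither stutter nor re-mutate)
apply_read_errors <- function(counts, stutter_rate, sub_rate) {
  add <- list()
  for (i in seq_len(nrow(counts))) {
    id <- counts$allele[i]
    r <- counts$reads[i]
    if (r == 0L || grepl("_e", id, fixed = TRUE)) next
    k <- as.integer(id)
    if (stutter_rate > 0 && k > 1L) {
      s <- stats::rbinom(1L, r, stutter_rate)
      if (s > 0L) {
        r <- r - s
        add[[length(add) + 1L]] <- data.frame(
          allele = as.character(k - 1L), reads = s,
          stringsAsFactors = FALSE)
      }
    }
    if (sub_rate > 0 && r > 0L) {
      e <- stats::rbinom(1L, r, sub_rate)
      if (e > 0L) {
        r <- r - e
        e1 <- stats::rbinom(1L, e, 0.5)
        for (j in c(1L, 2L)) {
          cnt <- if (j == 1L) e1 else e - e1
          if (cnt > 0L) {
            add[[length(add) + 1L]] <- data.frame(
              allele = paste0(k, "_e", j), reads = cnt,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    counts$reads[i] <- r
  }
  out <- rbind(counts, do.call(rbind, add))
  out <- aggregate(reads ~ allele, data = out, FUN = sum)
  out[out$reads > 0, , drop = FALSE]
}

#' Simulate tissue read counts for genotyped individuals
#'
#' Per individual and locus, a negative-binomial depth around
#' `tissue_depth / n_loci` is split between the two true alleles with a
#' mild Beta-distributed amplification bias; stutter then moves reads to
#' the one-repeat-shorter allele and substitution errors create
#' erroneous sequence variants.
#'
#' @inheritParams gen_mesocosms
#' @param genotypes genotype data frame of the individuals to sequence.
#' @param panel the `locus_panel`.
#' @return a read count table (`sample` = individual, `locus`, `allele`,
#'   `reads`).
#' @export
gen_tissue_reads <- function(genotypes, panel, config = sim_config(),
                             seed = NULL) {
  maybe_with_seed(seed, {
    mu <- config$tissue_depth / config$n_loci
    rows <- list()
    g <- genotypes[!is.na(genotypes$allele1), , drop = FALSE]
    for (i in seq_len(nrow(g))) {
      depth <- stats::rnbinom(1L, mu = mu, size = config$depth_dispersion)
      if (depth == 0L) next
      a <- c(g$allele1[i], g$allele2[i])
      if (a[1] == a[2]) {
        counts <- data.frame(allele = a[1], reads = depth,
                             stringsAsFactors = FALSE)
      } else {
        b <- stats::rbeta(1L, config$amp_bias_shape, config$amp_bias_shape)
        r1 <- stats::rbinom(1L, depth, b)
        counts <- data.frame(allele = a, reads = c(r1, depth - r1),
                             stringsAsFactors = FALSE)
      }
      counts <- apply_read_errors(counts, config$stutter_rate,
                                  config$sub_rate)
      if (nrow(counts) == 0L) next
      counts$sample <- g$individual[i]
      counts$locus <- g$locus[i]
      rows[[length(rows) + 1L]] <- counts
    }
    finish_count_table(rows)
  })
}

finish_count_table <- function(rows) {
  if (length(rows) == 0L) {
    return(data.frame(sample = character(), locus = character(),
                      allele = character(), reads = integer()))
  }
  out <- do.call(rbind, rows)[c("sample", "locus", "allele", "reads")]
  out <- out[order(out$sample, out$locus, out$allele), ]
  out$reads <- as.integer(out$reads)
  rownames(out) <- NULL
  out
}

#' Simulate eDNA read counts for one group of contributors
#'
#' Contribution weights are a symmetric Dirichlet draw over the member
#' individuals (shared across replicate samples: the inequality is a
#' property of the animals, not of the water bottle).  Per replicate and
#' locus, expected allele proportions are the weight-averaged genotype
#' dosages; counts are multinomial at a negative-binomial locus depth;
#' allelic dropout zeroes an allele's reads with probability inflated
#' for low-contribution alleles; stutter and substitution errors follow.
#'
#' @inheritParams gen_tissue_reads
#' @param genotypes genotype data frame of the member individuals only.
#' @param unit label used to build sample identifiers
#'   (`"<unit>_e<replicate>"`).
#' @param depth target total reads per replicate sample.
#' @param n_replicates number of replicate water samples.
#' @return list with `counts` (read count table, one sample per
#'   replicate) and `weights` (data frame `individual`, `weight`).
#' @export
gen_edna_reads <- function(genotypes, panel, config = sim_config(),
                           unit = "unit", depth = config$edna_depth,
                           n_replicates = config$edna_replicates,
                           seed = NULL) {
  maybe_with_seed(seed, {
    members <- sort(unique(genotypes$individual))
    n_mem <- length(members)
    if (n_mem == 0L) stop("no member genotypes", call. = FALSE)
    w <- rdirichlet1(n_mem, config$weight_concentration)
    names(w) <- members
    mu <- depth / config$n_loci
    rows <- list()
    g <- genotypes[!is.na(genotypes$allele1), , drop = FALSE]
    by_locus <- split(g, g$locus)
    for (rep_i in seq_len(n_replicates)) {
      sample_id <- paste0(unit, "_e", rep_i)
      for (loc in names(by_locus)) {
        gl <- by_locus[[loc]]
        wm <- w[gl$individual]
        share <- tapply(c(wm / 2, wm / 2), c(gl$allele1, gl$allele2), sum)
        share <- share / sum(share)
        depth_l <- stats::rnbinom(1L, mu = mu,
                                  size = config$depth_dispersion)
        if (depth_l == 0L) next
        reads <- as.integer(stats::rmultinom(1L, depth_l,
                                             as.numeric(share)))
        counts <- data.frame(allele = names(share), reads = reads,
                             stringsAsFactors = FALSE)
        if (config$dropout_rate > 0) {
          p_drop <- pmin(0.9, config$dropout_rate /
                           (n_mem * as.numeric(share)))
          drop <- stats::runif(nrow(counts)) < p_drop
          counts$reads[drop] <- 0L
        }
        counts <- counts[counts$reads > 0, , drop = FALSE]
        if (nrow(counts) == 0L) next
        counts <- apply_read_errors(counts, config$stutter_rate,
                                    config$sub_rate)
        if (nrow(counts) == 0L) next
        counts$sample <- sample_id
        counts$locus <- loc
        rows[[length(rows) + 1L]] <- counts
      }
    }
    list(counts = finish_count_table(rows),
         weights = data.frame(individual = members, weight = as.numeric(w),
                              stringsAsFactors = FALSE))
  })
}

#' Write read counts as paired-end FASTQ
#'
#' Emits one forward/reverse FASTQ pair per sample; every counted read
#' becomes a read pair covering the full amplicon (truncated at
#' `read_len`), so pairs overlap along their whole length.  Qualities
#' are constant at `qual`; the default emission is error-free and
#' round-trips exactly through [fastq_to_counts()].
#'
#' @param counts read count table whose allele identifiers the panel can
#'   sequence (see [allele_sequence()]).
#' @param panel the `locus_panel`.
#' @param dir output directory (created if needed).
#' @param qual constant Phred score written for every base.
#' @param read_len maximum read length.
#' @return data frame (`sample`, `fwd`, `rev`) of written file paths,
#'   suitable as input to [fastq_to_counts()].
#' @export
emit_fastq <- function(counts, panel, dir, qual = 35L, read_len = 250L) {
  counts <- as_read_count_table(counts)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  loci <- panel_loci_df(panel)
  seq_cache <- new.env(parent = emptyenv())
  out <- list()
  for (sm in unique(counts$sample)) {
    cs <- counts[counts$sample == sm & counts$reads > 0, , drop = FALSE]
    fwd <- character(0)
    rev <- character(0)
    ids <- character(0)
    for (i in seq_len(nrow(cs))) {
      key <- paste(cs$locus[i], cs$allele[i], sep = "\r")
      if (is.null(seq_cache[[key]])) {
        seq_cache[[key]] <- allele_sequence(panel, cs$locus[i], cs$allele[i])
      }
      s <- seq_cache[[key]]
      if (nchar(s) < 2L * 20L) {
        stop("allele sequence too short to sequence: ", key, call. = FALSE)
      }
      f <- substr(s, 1L, min(read_len, nchar(s)))
      r <- substr(revcomp_chr(s), 1L, min(read_len, nchar(s)))
      n <- cs$reads[i]
      fwd <- c(fwd, rep(f, n))
      rev <- c(rev, rep(r, n))
      ids <- c(ids, sprintf("%s:%s:%s:%d", sm, cs$locus[i], cs$allele[i],
                            seq_len(n)))
    }
    fwd_path <- file.path(dir, paste0(sm, "_R1.fastq"))
    rev_path <- file.path(dir, paste0(sm, "_R2.fastq"))
    write_fastq(ids, fwd, qual, fwd_path)
    write_fastq(ids, rev, qual, rev_path)
    out[[length(out) + 1L]] <- data.frame(sample = sm, fwd = fwd_path,
                                          rev = rev_path,
                                          stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

write_fastq <- function(ids, seqs, qual, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  q <- Biostrings::BStringSet(strrep(intToUtf8(qual + 33L), nchar(seqs)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Simulate a full study
#'
#' Orchestrates the generators into one ground-truthed data set: panel,
#' population, mesocosm memberships, tissue read counts for all
#' genotyped individuals, replicate eDNA read counts per mesocosm, and a
#' field trial (extra unseen contributors sequenced at low depth in
#' triplicate).
#'
#' @param config a [sim_config()].
#' @param seed integer seed; the whole study is a pure function of
#'   (config, seed).
#' @return a `synthetic_truth` list: `config`, `seed`, `panel`,
#'   `pop_freqs`, `genotypes` (all genotyped individuals), `mesocosms`,
#'   `mesocosm_weights`, `tissue_counts`, `edna_counts`,
#'   `edna_replicate_map`, and `field` (`genotypes`, `counts`,
#'   `weights`, `true_contributors`).
#' @export
simulate_study <- function(config = sim_config(), seed = 1L) {
  withr::with_seed(seed, {
    panel <- gen_panel(config)
    pop <- gen_population(panel, config)
    mesocosms <- gen_mesocosms(pop$genotypes, config)
    tissue_counts <- gen_tissue_reads(pop$genotypes, panel, config)
    edna_rows <- list()
    weight_rows <- list()
    for (u in unique(mesocosms$unit)) {
      members <- mesocosms$individual[mesocosms$unit == u]
      gm <- pop$genotypes[pop$genotypes$individual %in% members, ,
                          drop = FALSE]
      sim <- gen_edna_reads(gm, panel, config, unit = u,
                            depth = config$edna_depth,
                            n_replicates = config$edna_replicates)
      edna_rows[[u]] <- sim$counts
      weight_rows[[u]] <- cbind(unit = u, sim$weights,
                                stringsAsFactors = FALSE)
    }
    edna_counts <- do.call(rbind, edna_rows)
    rownames(edna_counts) <- NULL
    replicate_map <- unique(data.frame(
      sample = edna_counts$sample,
      unit = sub("_e[0-9]+$", "", edna_counts$sample),
      stringsAsFactors = FALSE))
    field_geno <- gen_population(panel, config,
                                 n_individuals = config$field_contributors,
                                 freqs = pop$freqs)
    field_geno$genotypes$individual <-
      paste0("f", field_geno$genotypes$individual)
    field_sim <- gen_edna_reads(field_geno$genotypes, panel, config,
                                unit = "field",
                                depth = config$field_depth,
                                n_replicates = config$field_replicates)
    structure(
      list(config = config, seed = seed, panel = panel,
           pop_freqs = pop$freqs, genotypes = pop$genotypes,
           mesocosms = mesocosms,
           mesocosm_weights = do.call(rbind, weight_rows),
           tissue_counts = tissue_counts, edna_counts = edna_counts,
           edna_replicate_map = replicate_map,
           field = list(genotypes = field_geno$genotypes,
                        counts = field_sim$counts,
                        weights = field_sim$weights,
                        true_contributors = config$field_contributors)),
      class = "synthetic_truth")
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic eDNA microsatellite study (seed", x$seed, ")\n")
  cat("  loci:", x$config$n_loci,
      "| genotyped individuals:", length(unique(x$genotypes$individual)),
      "\n")
  cat("  mesocosms:", length(unique(x$mesocosms$unit)), "units,",
      nrow(x$mesocosms), "fish\n")
  cat("  tissue count rows:", nrow(x$tissue_counts),
      "| eDNA count rows:", nrow(x$edna_counts), "\n")
  invisible(x)
}
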