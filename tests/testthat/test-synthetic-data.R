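test_that("every generator is a pure function of its seed", {
  cfg <- small_config()
  p1 <- gen_panel(cfg, seed = 5)
  p2 <- gen_panel(cfg, seed = 5)
  expect_identical(p1, p2)
  pop1 <- gen_population(p1, cfg, n_individuals = 10, seed = 6)
  pop2 <- gen_population(p1, cfg, n_individuals = 10, seed = 6)
  expect_identical(pop1, pop2)
  e1 <- gen_edna_reads(pop1$genotypes, p1, cfg, seed = 7)
  e2 <- gen_edna_reads(pop1$genotypes, p1, cfg, seed = 7)
  expect_identical(e1, e2)
  expect_false(identical(gen_panel(cfg, seed = 5), gen_panel(cfg, seed = 6)))
})

test_that("the default panel matches the study design", {
  panel <- gen_panel(sim_config(), seed = 1)
  expect_identical(nrow(panel$loci), 28L)
  expect_true(all(panel$loci$richness >= 2 & panel$loci$richness <= 21))
  expect_false(anyDuplicated(panel$loci$fwd_primer) > 0)
  # all alleles of a locus share the 40 bp reference prefix
  for (loc in panel$loci$locus[1:5]) {
    seqs <- panel$alleles$sequence[panel$alleles$locus == loc]
    expect_identical(length(unique(substr(seqs, 1, 40))), 1L)
    expect_identical(unique(substr(seqs, 1, 40)),
                     panel$loci$reference_prefix[panel$loci$locus == loc])
  }
})

test_that("panel richness concentrates around its configured mean", {
  set.seed(77)
  means <- replicate(30, mean(gen_panel(sim_config())$loci$richness))
  # mean of 28 binomial(19, .3895) draws, 30 panels: 3 SE band
  se <- sqrt(19 * 0.3895 * (1 - 0.3895) / (28 * 30))
  expect_lt(abs(mean(means) - 9.4), 3 * se)
})

test_that("population genotypes follow Hardy-Weinberg expectations", {
  cfg <- small_config(n_loci = 4L)
  panel <- gen_panel(cfg, seed = 11)
  pop <- gen_population(panel, cfg, n_individuals = 500, seed = 12)
  sums <- tapply(pop$freqs$freq, pop$freqs$locus, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  for (loc in unique(pop$freqs$locus)) {
    p <- pop$freqs$freq[pop$freqs$locus == loc]
    g <- pop$genotypes[pop$genotypes$locus == loc, ]
    het_exp <- 1 - sum(p^2)
    het_obs <- mean(g$allele1 != g$allele2)
    se <- sqrt(het_exp * (1 - het_exp) / 500)
    expect_lt(abs(het_obs - het_exp), 3 * se + 1e-9)
  }
})

test_that("mesocosm assignment reproduces the stocking design", {
  cfg <- sim_config()
  panel <- gen_panel(cfg, seed = 1)
  pop <- gen_population(panel, cfg, seed = 2)
  m <- gen_mesocosms(pop$genotypes, cfg, seed = 3)
  expect_identical(nrow(m), 58L)
  expect_false(anyDuplicated(m$individual) > 0)
  sizes <- sort(as.integer(table(m$unit)))
  expect_identical(sizes, sort(c(1L, 1L, 1L, 3L, 3L, 3L, 5L, 5L, 5L,
                                 10L, 10L, 11L)))
  expect_identical(sum(table(m$unit)["10c"]), 11L)
  few <- pop$genotypes[pop$genotypes$individual %in%
                         sprintf("i%03d", 1:10), ]
  expect_error(gen_mesocosms(few, cfg), "at least 58")
})

test_that("error-free tissue reads land on the true alleles", {
  cfg <- small_config(sub_rate = 0, stutter_rate = 0, dropout_rate = 0,
                      n_loci = 5L, tissue_depth = 5000)
  panel <- gen_panel(cfg, seed = 31)
  pop <- gen_population(panel, cfg, n_individuals = 6, seed = 32)
  counts <- gen_tissue_reads(pop$genotypes, panel, cfg, seed = 33)
  merged <- merge(counts, pop$genotypes,
                  by.x = c("sample", "locus"),
                  by.y = c("individual", "locus"))
  expect_true(all(merged$allele == merged$allele1 |
                    merged$allele == merged$allele2))
  # heterozygotes at depth ~1000: both alleles clear the 20% call rule
  het <- merged[merged$allele1 != merged$allele2, ]
  tot <- ave(het$reads, paste(het$sample, het$locus), FUN = sum)
  expect_true(all(het$reads / tot >= 0.2))
})

test_that("stutter moves the configured fraction of reads one repeat down", {
  cfg <- small_config(sub_rate = 0, stutter_rate = 0.05, dropout_rate = 0,
                      n_loci = 20L, tissue_depth = 40000)
  panel <- gen_panel(cfg, seed = 41)
  pop <- gen_population(panel, cfg, n_individuals = 4, seed = 42)
  # homozygous-only genotypes so parent and stutter alleles are unambiguous
  g <- pop$genotypes
  g$allele2 <- g$allele1
  counts <- gen_tissue_reads(g, panel, cfg, seed = 43)
  parent <- merge(counts, g[c("individual", "locus", "allele1")],
                  by.x = c("sample", "locus"),
                  by.y = c("individual", "locus"))
  is_parent <- parent$allele == parent$allele1
  is_stutter <- parent$allele ==
    as.character(as.integer(parent$allele1) - 1L)
  frac <- sum(parent$reads[is_stutter]) /
    (sum(parent$reads[is_stutter]) + sum(parent$reads[is_parent]))
  n <- sum(parent$reads[is_stutter | is_parent])
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / n))
})

test_that("eDNA reads mirror contributor dosage and converge with depth", {
  cfg <- small_config(sub_rate = 0, stutter_rate = 0, dropout_rate = 0,
                      n_loci = 6L)
  panel <- gen_panel(cfg, seed = 51)
  pop <- gen_population(panel, cfg, n_individuals = 5, seed = 52)
  # single member: allele proportions equal genotype dosage
  g1 <- pop$genotypes[pop$genotypes$individual == "i001", ]
  sim1 <- gen_edna_reads(g1, panel, cfg, unit = "solo", depth = 2e5,
                         n_replicates = 1, seed = 53)
  freqs1 <- edna_allele_freqs(scale_to_100(sim1$counts))
  hom <- g1[g1$allele1 == g1$allele2, ]
  for (i in seq_len(nrow(hom))) {
    f <- freqs1[freqs1$locus == hom$locus[i], ]
    expect_identical(f$allele, hom$allele1[i])
    expect_equal(f$freq, 1)
  }
  het <- g1[g1$allele1 != g1$allele2, ][1, ]
  f_het <- freqs1[freqs1$locus == het$locus, ]
  expect_equal(sort(f_het$freq), sort(c(0.5, 0.5)), tolerance = 0.05)
  # many members, equal weights, huge depth: locus frequencies converge
  # to the pooled true allele frequencies of the group
  cfg_eq <- small_config(sub_rate = 0, stutter_rate = 0, dropout_rate = 0,
                         n_loci = 6L, weight_concentration = 1e6)
  sim_all <- gen_edna_reads(pop$genotypes, panel, cfg_eq, unit = "all",
                            depth = 1e6, n_replicates = 1, seed = 54)
  freqs_all <- edna_allele_freqs(scale_to_100(sim_all$counts))
  pooled_truth <- pop_allele_freqs(pop$genotypes)
  cmp <- align_and_correlate(freqs_all, pooled_truth)
  expect_lt(max(abs(cmp$aligned$freq1 - cmp$aligned$freq2)), 0.01)
})

test_that("FASTQ emission writes one valid pair per counted read", {
  cfg <- small_config(n_loci = 2L, tissue_depth = 100, sub_rate = 0,
                      stutter_rate = 0, dropout_rate = 0)
  panel <- gen_panel(cfg, seed = 61)
  pop <- gen_population(panel, cfg, n_individuals = 1, seed = 62)
  counts <- gen_tissue_reads(pop$genotypes, panel, cfg, seed = 63)
  dir <- withr::local_tempdir()
  samples <- emit_fastq(counts, panel, dir)
  fwd <- Biostrings::readDNAStringSet(samples$fwd[1], format = "fastq",
                                      with.qualities = TRUE)
  rev <- Biostrings::readDNAStringSet(samples$rev[1], format = "fastq",
                                      with.qualities = TRUE)
  expect_identical(length(fwd), sum(counts$reads))
  expect_identical(length(rev), sum(counts$reads))
  expect_identical(Biostrings::width(fwd),
                   Biostrings::width(S4Vectors::mcols(fwd)$qualities))
  # four lines per record in the raw file
  expect_identical(length(readLines(samples$fwd[1])) %% 4L, 0L)
})
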