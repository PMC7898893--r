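test_that("quality trimming truncates at the first failing window", {
  good <- quality_trim("ACGTACGTAC", rep(30L, 10))
  expect_identical(good$bases, "ACGTACGTAC")
  expect_null(quality_trim("ACGTACGTAC", rep(10L, 10)))
  # 20 high-quality bases then a low tail: the first window whose mean
  # drops below 20 starts at position 20, so 19 bases survive
  mixed <- quality_trim(strrep("A", 40), c(rep(30L, 20), rep(10L, 20)))
  expect_identical(nchar(mixed$bases), 19L)
  expect_true(all(mixed$quals == 30L))
  # shorter than the minimum length after trimming: discarded
  expect_null(quality_trim(strrep("A", 40), c(rep(30L, 20), rep(10L, 20)),
                           min_len = 25L))
})

test_that("pair merging honours overlap and mismatch constraints", {
  set.seed(17)
  template <- paste(sample(c("A", "C", "G", "T"), 90, TRUE), collapse = "")
  fwd <- substr(template, 1, 60)
  rev_tmpl <- substr(template, 31, 90)    # 30 bp overlap with fwd
  rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(rev_tmpl)))
  q60 <- rep(30L, 60)
  m <- merge_pairs(fwd, q60, rev, q60)
  expect_identical(m$bases, template)
  expect_identical(nchar(m$bases), 60L + 60L - 30L)
  # best available overlap only 19 bp: failure
  short_rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(paste0(substr(template, 42, 90),
                                 strrep("A", 30)))))
  expect_null(merge_pairs(fwd, q60, short_rev, rep(30L, nchar(short_rev)),
                          min_overlap = 20L))
  # 3 mismatches in a 40 bp overlap (7.5% >= 5%): failure
  bad_tmpl <- rev_tmpl
  for (pos in c(2, 10, 18)) {
    b <- substr(bad_tmpl, pos, pos)
    substr(bad_tmpl, pos, pos) <- chartr("ACGT", "CGTA", b)
  }
  bad_rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(bad_tmpl, 1, 40))))
  expect_null(merge_pairs(substr(template, 1, 70), rep(30L, 70), bad_rev,
                          rep(30L, 40), min_overlap = 40L))
  # a single disagreement is resolved toward the higher-quality base
  one_mm <- rev_tmpl
  substr(one_mm, 5, 5) <- chartr("ACGT", "CGTA", substr(one_mm, 5, 5))
  mm_rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(one_mm)))
  hi_rev_q <- rep(38L, 60)
  merged <- merge_pairs(fwd, q60, mm_rev, hi_rev_q)
  expect_identical(substr(merged$bases, 35, 35), substr(one_mm, 5, 5))
})

test_that("locus assignment requires an unambiguous primer match", {
  panel <- list(loci = data.frame(
    locus = c("L1", "L2"),
    fwd_primer = c("ACGTACGTACGTACGTACGT", "TGCATGCATGCATGCATGCA"),
    stringsAsFactors = FALSE))
  expect_identical(assign_locus(paste0("ACGTACGTACGTACGTACGT", "AAAA"),
                                panel), "L1")
  miss <- assign_locus("GGGGGGGGGGGGGGGGGGGGGGGG", panel)
  expect_true(is.na(miss))
  expect_identical(attr(miss, "reason"), "unassigned")
  one_mm <- paste0("CCGTACGTACGTACGTACGT", "AAAA")
  expect_true(is.na(assign_locus(one_mm, panel)))
  expect_identical(assign_locus(one_mm, panel,
                                max_primer_mismatches = 1L), "L1")
})

test_that("the reference-prefix filter applies 90% identity over 40 bp", {
  ref <- strrep("ACGT", 12)
  mutate_at <- function(s, idx) {
    for (i in idx) substr(s, i, i) <- chartr("ACGT", "CGTA", substr(s, i, i))
    s
  }
  # 4 mismatches in the first 40 positions -> exactly 90% identity
  expect_true(reference_filter(mutate_at(ref, 37:40), ref))
  # 5 mismatches -> 87.5%
  expect_false(reference_filter(mutate_at(ref, 36:40), ref))
  expect_true(reference_filter(ref, ref))
  expect_false(reference_filter(substr(ref, 1, 39), ref))  # too short
})

test_that("identical contigs collapse to counts", {
  out <- collapse_reads(c("AAA", "AAA", "AAA", "CCC"))
  expect_identical(out$count, c(3L, 1L))
  expect_identical(out$sequence, c("AAA", "CCC"))
  expect_identical(nrow(collapse_reads(character(0))), 0L)
})

test_that("error-free FASTQ round-trips exactly with full accounting", {
  cfg <- sim_config(n_loci = 3, tissue_depth = 150, sub_rate = 0,
                    stutter_rate = 0, dropout_rate = 0)
  panel <- gen_panel(cfg, seed = 8)
  pop <- gen_population(panel, cfg, n_individuals = 2, seed = 9)
  counts <- gen_tissue_reads(pop$genotypes, panel, cfg, seed = 10)
  dir <- withr::local_tempdir()
  samples <- emit_fastq(counts, panel, dir)
  res <- fastq_to_counts(samples, panel)
  expect_equal(res$counts[c("sample", "locus", "allele", "reads")], counts,
               ignore_attr = TRUE)
  # conservation: pairs in = discarded + failed + unassigned + filtered
  # + counted, and the counted reads are really in the table
  with(res$stats, expect_identical(
    n_pairs, n_quality_discarded + n_merge_failed + n_unassigned +
      n_reference_filtered + n_counted))
  tab_sums <- tapply(res$counts$reads, res$counts$sample, sum)
  expect_identical(as.integer(tab_sums[res$stats$sample]),
                   res$stats$n_counted)
  # deterministic under read order: shuffle the FASTQ records
  f1 <- Biostrings::readDNAStringSet(samples$fwd[1], format = "fastq",
                                     with.qualities = TRUE)
  r1 <- Biostrings::readDNAStringSet(samples$rev[1], format = "fastq",
                                     with.qualities = TRUE)
  set.seed(6)
  ord <- sample(length(f1))
  shuf_dir <- withr::local_tempdir()
  fwd2 <- file.path(shuf_dir, "s_R1.fastq")
  rev2 <- file.path(shuf_dir, "s_R2.fastq")
  Biostrings::writeXStringSet(f1[ord], fwd2, format = "fastq",
                              qualities = S4Vectors::mcols(f1)$qualities[ord])
  Biostrings::writeXStringSet(r1[ord], rev2, format = "fastq",
                              qualities = S4Vectors::mcols(r1)$qualities[ord])
  res2 <- fastq_to_counts(
    data.frame(sample = samples$sample[1], fwd = fwd2, rev = rev2), panel)
  orig1 <- res$counts[res$counts$sample == samples$sample[1], ]
  expect_equal(res2$counts$reads[match(orig1$sequence,
                                       res2$counts$sequence)],
               orig1$reads)
})

test_that("off-panel reads are unassigned and empty FASTQ yields no counts", {
  cfg <- sim_config(n_loci = 2, tissue_depth = 60, sub_rate = 0,
                    stutter_rate = 0, dropout_rate = 0)
  panel_a <- gen_panel(cfg, seed = 21)
  panel_b <- gen_panel(cfg, seed = 22)    # different primers
  pop <- gen_population(panel_a, cfg, n_individuals = 1, seed = 23)
  counts <- gen_tissue_reads(pop$genotypes, panel_a, cfg, seed = 24)
  dir <- withr::local_tempdir()
  samples <- emit_fastq(counts, panel_a, dir)
  res <- fastq_to_counts(samples, panel_b)
  expect_identical(sum(res$stats$n_counted), 0L)
  expect_identical(sum(res$stats$n_unassigned), sum(res$stats$n_pairs))
  # empty FASTQ
  empty_dir <- withr::local_tempdir()
  e1 <- file.path(empty_dir, "e_R1.fastq")
  e2 <- file.path(empty_dir, "e_R2.fastq")
  file.create(e1, e2)
  res_e <- fastq_to_counts(data.frame(sample = "e", fwd = e1, rev = e2),
                           panel_a)
  expect_identical(nrow(res_e$counts), 0L)
  expect_identical(res_e$stats$n_pairs, 0L)
})
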