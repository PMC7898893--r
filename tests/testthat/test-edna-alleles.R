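test_that("minimum-read filter removes sub-threshold alleles per sample", {
  tab <- rct("s1", "L1", c("a", "b", "c"), c(9, 10, 120))
  out <- min_read_filter(tab)
  expect_setequal(out$allele, c("b", "c"))   # 9 removed, boundary 10 kept
  empty <- min_read_filter(tab[0, ])
  expect_identical(nrow(empty), 0L)
})

test_that("scaling to 100 preserves within-locus proportions exactly", {
  tab <- rct("s1", "L1", c("a", "b"), c(900, 100))
  out <- scale_to_100(tab)
  expect_equal(out$scaled_reads, c(90, 10))
  single <- scale_to_100(rct("s1", "L1", "a", 37))
  expect_equal(single$scaled_reads, 100)
  thirds <- scale_to_100(rct("s1", "L1", c("a", "b"), c(1, 2)))
  expect_equal(thirds$scaled_reads, c(100 / 3, 200 / 3))
  # proportions preserved on random tables
  set.seed(3)
  tab <- rct("s1", rep(c("L1", "L2"), each = 4), rep(letters[1:4], 2),
             sample(1:500, 8))
  out <- scale_to_100(tab)
  for (loc in c("L1", "L2")) {
    a <- tab[tab$locus == loc, ]
    b <- out[out$locus == loc, ]
    expect_equal(b$scaled_reads / sum(b$scaled_reads),
                 a$reads / sum(a$reads), tolerance = 1e-12)
    expect_equal(sum(b$scaled_reads), 100, tolerance = 1e-9)
  }
})

test_that("the low-frequency filter acts per sample without re-scaling", {
  sc <- scale_to_100(rct("s1", "L1", c("a", "b"), c(992, 8)))
  out <- low_freq_filter(sc)
  expect_identical(out$allele, "a")           # 0.8% removed
  expect_equal(out$scaled_reads, 99.2)        # not re-scaled
  boundary <- low_freq_filter(scale_to_100(rct("s1", "L1", c("a", "b"),
                                               c(990, 10))))
  expect_setequal(boundary$allele, c("a", "b"))   # exactly 1% kept
  lone <- low_freq_filter(scale_to_100(rct("s1", "L1", "a", 100)))
  expect_equal(lone$scaled_reads, 100)
})

test_that("replicate pooling sums scaled counts and unions loci", {
  sc <- rbind(
    data.frame(sample = "r1", locus = "L1", allele = c("a", "b"),
               scaled_reads = c(90, 10)),
    data.frame(sample = "r2", locus = "L1", allele = c("a", "b"),
               scaled_reads = c(80, 20)),
    data.frame(sample = "r1", locus = "L2", allele = "c",
               scaled_reads = 100))
  map <- data.frame(sample = c("r1", "r2"), unit = "m1")
  out <- pool_replicates(sc, map)
  expect_equal(out$scaled_reads[out$locus == "L1"], c(170, 30))
  # L2 only in r1: union taken
  expect_equal(out$scaled_reads[out$locus == "L2"], 100)
  # single replicate is the identity
  solo <- pool_replicates(sc[sc$sample == "r1", ],
                          data.frame(sample = "r1", unit = "m1"))
  expect_equal(sort(solo$scaled_reads), sort(c(90, 10, 100)))
})

test_that("eDNA allele frequencies are read frequencies summing to one", {
  pooled <- data.frame(sample = "m1", locus = "L1", allele = c("a", "b"),
                       scaled_reads = c(170, 30))
  f <- edna_allele_freqs(pooled)
  expect_equal(f$freq, c(0.85, 0.15))
  one <- edna_allele_freqs(data.frame(sample = "m1", locus = "L1",
                                      allele = "a", scaled_reads = 100))
  expect_equal(one$freq, 1)
  set.seed(9)
  big <- data.frame(sample = "m1", locus = rep(c("L1", "L2", "L3"), each = 5),
                    allele = rep(letters[1:5], 3),
                    scaled_reads = runif(15, 0.1, 60))
  f <- edna_allele_freqs(big)
  sums <- tapply(f$freq, f$locus, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("the variable threshold interpolates log-linearly in richness", {
  sch <- threshold_scheme("variable")
  expect_equal(variable_threshold(2, sch), 0.1)
  expect_equal(variable_threshold(21, sch), 0.001)
  expect_equal(variable_threshold(11.5, sch), 0.01, tolerance = 1e-12)
  # clamped outside the range, non-increasing within
  expect_equal(variable_threshold(1, sch), 0.1)
  expect_equal(variable_threshold(40, sch), 0.001)
  r <- seq(2, 21, by = 0.5)
  expect_true(all(diff(variable_threshold(r, sch)) < 0))
})

test_that("threshold filtering respects the scheme and is monotone in t", {
  sc <- data.frame(sample = "m1", locus = "L1",
                   allele = c("a", "b"), scaled_reads = c(95, 5))
  out <- threshold_filter(sc, threshold_scheme("fixed", t = 0.1))
  expect_identical(out$allele, "a")
  out2 <- threshold_filter(sc, threshold_scheme("fixed", t = 0.001))
  expect_setequal(out2$allele, c("a", "b"))
  # a 2-allele locus behaves as t = 0.1 under the variable scheme
  var_out <- threshold_filter(sc, threshold_scheme("variable"),
                              richness = c(L1 = 2L))
  expect_identical(var_out$allele, "a")
  # monotone nesting of survivors across stricter thresholds
  set.seed(21)
  tab <- data.frame(sample = "m1", locus = rep(c("L1", "L2"), each = 8),
                    allele = rep(letters[1:8], 2),
                    scaled_reads = runif(16, 0.01, 40))
  keys <- function(t) {
    o <- threshold_filter(tab, threshold_scheme("fixed", t = t))
    paste(o$locus, o$allele)
  }
  expect_true(all(keys(0.1) %in% keys(0.01)))
  expect_true(all(keys(0.01) %in% keys(0.001)))
})

test_that("mixture profiles keep only population-known alleles", {
  filt <- data.frame(sample = "m1", locus = c("L1", "L1", "L2"),
                     allele = c("a", "b", "c"),
                     scaled_reads = c(60, 40, 100))
  pop <- rbind(data.frame(locus = "L1", allele = "a", freq = 1))
  prof <- to_mixture_profile(filt, pop)
  expect_identical(prof$allele, "a")
  expect_identical(attr(prof, "n_dropped_alleles"), 2L)
  expect_false("L2" %in% prof$locus)    # emptied locus absent, not empty
  # population superset: identity
  pop2 <- rbind(data.frame(locus = "L1", allele = c("a", "b", "z"),
                           freq = c(0.5, 0.3, 0.2)),
                data.frame(locus = "L2", allele = "c", freq = 1))
  prof2 <- to_mixture_profile(filt, pop2)
  expect_identical(nrow(prof2), 3L)
  expect_identical(attr(prof2, "n_dropped_alleles"), 0L)
})

test_that("the pipeline scales replicates before pooling them", {
  # unequal-depth replicates: scaling first weights them equally, so the
  # pooled frequencies are 50/50 rather than depth-weighted 1000:100
  tab <- rbind(rct("r1", "L1", "a", 1000), rct("r2", "L1", "b", 100))
  map <- data.frame(sample = c("r1", "r2"), unit = "m1")
  pooled <- edna_pipeline(tab, replicate_map = map, low_freq = NULL)
  f <- edna_allele_freqs(pooled)
  expect_equal(f$freq, c(0.5, 0.5))
})
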