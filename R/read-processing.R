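#' @title Amplicon read processing
#'
#' @description
#' Converts demultiplexed, adapter-free paired-end amplicon FASTQ into a
#' per-sample x locus x allele read count table: 3' quality trimming,
#' overlap-based pair merging, forward-primer locus assignment, exact
#' collapsing of identical contigs, and a reference-prefix identity
#' filter that removes PCR artifacts and paralogous amplicons.  Every
#' read pair is accounted for: pairs in = quality-discarded +
#' merge-failed + unassigned + reference-filtered + counted, per sample.
#' @name read_processing
NULL

#' 3' sliding-window quality trim
#'
#' Scans windows of `window` consecutive Phred scores from the 5' end and
#' truncates the read immediately before the first window whose mean
#' quality drops below `q_min`.  Reads shorter than `min_len` after
#' trimming are discarded.
#'
#' @param bases read sequence (single character string).
#' @param quals integer vector of per-base Phred scores, one per base.
#' @param q_min minimum mean window quality.
#' @param window sliding window width.
#' @param min_len minimum surviving length (typically the forward primer
#'   length); shorter results are discarded.
#' @return list with `bases` and `quals`, or `NULL` when discarded.
#' @export
quality_trim <- function(bases, quals, q_min = 20, window = 4L,
                         min_len = 1L) {
  len <- nchar(bases)
  if (len != length(quals)) {
    stop("sequence and quality lengths differ", call. = FALSE)
  }
  if (len == 0L) return(NULL)
  if (min(quals) >= q_min) {      # nothing to trim
    if (len < min_len) return(NULL)
    return(list(bases = bases, quals = quals))
  }
  if (len < window) {
    cut <- if (mean(quals) < q_min) 0L else len
  } else {
    wmean <- as.numeric(stats::filter(quals, rep(1 / window, window),
                                      sides = 1))
    wmean <- wmean[window:len]          # mean of windows ending at window..len
    bad <- which(wmean < q_min)
    # window i (1-based start) spans start i .. i+window-1
    cut <- if (length(bad) == 0L) len else bad[1] - 1L
  }
  if (cut < min_len) return(NULL)
  list(bases = substr(bases, 1L, cut), quals = quals[seq_len(cut)])
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Merge a read pair into an amplicon contig
#'
#' The reverse mate is reverse-complemented and the longest overlap of at
#' least `min_overlap` bases with a mismatch rate strictly below
#' `max_mismatch_rate` is accepted; base disagreements within the overlap
#' are resolved in favour of the higher Phred score.
#'
#' @param fwd,rev read sequences (character strings); `rev` in sequencing
#'   orientation (reverse-complement of the template strand).
#' @param fwd_q,rev_q integer Phred scores for `fwd` and `rev`.
#' @inheritParams quality_trim
#' @param min_overlap minimum acceptable overlap length.
#' @param max_mismatch_rate overlap mismatch rate bound (strict: a rate
#'   of exactly this value fails).
#' @return list with `bases` and `quals` of the merged contig, or `NULL`
#'   when no acceptable overlap exists.
#' @export
merge_pairs <- function(fwd, fwd_q, rev, rev_q, min_overlap = 20L,
                        max_mismatch_rate = 0.05) {
  lf <- nchar(fwd)
  lr <- nchar(rev)
  if (lf < min_overlap || lr < min_overlap) return(NULL)
  rc <- revcomp_chr(rev)
  rq <- rev(rev_q)
  if (lf == lr && fwd == rc) {    # full-length exact overlap
    return(list(bases = fwd, quals = pmax(fwd_q, rq)))
  }
  f_raw <- charToRaw(fwd)
  r_raw <- charToRaw(rc)
  for (o in seq(min(lf, lr), min_overlap)) {
    f_tail <- f_raw[(lf - o + 1L):lf]
    r_head <- r_raw[seq_len(o)]
    mism <- which(f_tail != r_head)
    if (length(mism) / o < max_mismatch_rate) {
      fq_tail <- fwd_q[(lf - o + 1L):lf]
      rq_head <- rq[seq_len(o)]
      ov <- f_tail
      if (length(mism)) {
        use_r <- mism[rq_head[mism] > fq_tail[mism]]
        ov[use_r] <- r_head[use_r]
      }
      ov_q <- pmax(fq_tail, rq_head)
      bases <- paste0(substr(fwd, 1L, lf - o), rawToChar(as.raw(ov)),
                      substr(rc, o + 1L, lr))
      quals <- c(fwd_q[seq_len(lf - o)], ov_q, rq[(o + 1L):lr][seq_len(lr - o)])
      return(list(bases = bases, quals = quals))
    }
  }
  NULL
}

#' Assign a contig to a panel locus by its forward primer
#'
#' @param contig contig sequence (character string).
#' @param panel a locus panel (see [gen_panel()] or [read_panel()]); its
#'   `loci` data frame must hold `locus` and `fwd_primer`.
#' @param max_primer_mismatches mismatches tolerated in the primer
#'   prefix.
#' @return the locus identifier, or `NA` with attribute
#'   `reason = "unassigned"` / `"ambiguous"`.
#' @export
assign_locus <- function(contig, panel, max_primer_mismatches = 0L) {
  loci <- panel_loci_df(panel)
  c_raw <- charToRaw(contig)
  hits <- character()
  for (i in seq_len(nrow(loci))) {
    primer <- loci$fwd_primer[i]
    lp <- nchar(primer)
    if (nchar(contig) < lp) next
    mism <- sum(charToRaw(primer) != c_raw[seq_len(lp)])
    if (mism <= max_primer_mismatches) hits <- c(hits, loci$locus[i])
  }
  if (length(hits) == 1L) return(hits)
  out <- NA_character_
  attr(out, "reason") <- if (length(hits) == 0L) "unassigned" else "ambiguous"
  out
}

#' Reference-prefix identity filter
#'
#' Keeps a contig iff the ungapped identity of its first `span` bases
#' against the locus reference prefix (built from the most common allele)
#' is at least `min_identity`.  Contigs shorter than `span` are dropped.
#'
#' @param sequence contig sequence.
#' @param reference_prefix reference sequence of at least `span` bases.
#' @param min_identity minimum fraction of matching bases (boundary
#'   inclusive: exactly `min_identity` passes).
#' @param span number of leading bases compared.
#' @return logical: keep (`TRUE`) or drop (`FALSE`).
#' @export
reference_filter <- function(sequence, reference_prefix, min_identity = 0.9,
                             span = 40L) {
  if (nchar(reference_prefix) < span) {
    stop("reference prefix shorter than comparison span", call. = FALSE)
  }
  if (nchar(sequence) < span) return(FALSE)
  s <- charToRaw(substr(sequence, 1L, span))
  r <- charToRaw(substr(reference_prefix, 1L, span))
  sum(s == r) / span >= min_identity
}

#' Collapse identical contigs to sequence counts
#'
#' @param contigs character vector of contig sequences (one sample, one
#'   locus).
#' @return data frame (`sequence`, `count`) sorted by decreasing count.
#' @export
collapse_reads <- function(contigs) {
  if (length(contigs) == 0L) {
    return(data.frame(sequence = character(), count = integer()))
  }
  tab <- table(contigs)
  out <- data.frame(sequence = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$sequence), ]
  rownames(out) <- NULL
  out
}

read_fastq_file <- function(path) {
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq",
                                 with.qualities = TRUE),
    error = function(e) stop("malformed FASTQ in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  quals <- methods::as(
    Biostrings::PhredQuality(S4Vectors::mcols(x)$qualities), "IntegerList")
  list(id = names(x), seq = as.character(x), qual = as.list(quals))
}

#' Paired-end FASTQ to read count table
#'
#' Runs the full chain per sample: quality trimming of both mates,
#' pair merging, primer-based locus assignment, reference-prefix
#' filtering, and exact collapsing, then assigns stable allele
#' identifiers to identical sequences across all samples.  Allele
#' sequences known to the panel keep their panel identifiers; novel
#' sequences receive fresh per-locus identifiers in decreasing order of
#' total count.
#'
#' @param samples data frame with columns `sample`, `fwd`, `rev` (FASTQ
#'   paths, optionally gzipped).
#' @param panel locus panel with `loci` (`locus`, `fwd_primer`,
#'   `reference_prefix`) and optionally `alleles` (`locus`, `allele`,
#'   `sequence`) for identifier assignment.
#' @inheritParams quality_trim
#' @inheritParams merge_pairs
#' @inheritParams assign_locus
#' @inheritParams reference_filter
#' @return list with `counts` (data frame `sample`, `locus`, `allele`,
#'   `reads`, `sequence`) and `stats` (per-sample attrition: `n_pairs`,
#'   `n_quality_discarded`, `n_merge_failed`, `n_unassigned`,
#'   `n_reference_filtered`, `n_counted`).
#' @export
fastq_to_counts <- function(samples, panel, q_min = 20, window = 4L,
                            min_overlap = 20L, max_mismatch_rate = 0.05,
                            max_primer_mismatches = 0L, min_identity = 0.9,
                            span = 40L) {
  samples <- as.data.frame(samples)
  stopifnot(all(c("sample", "fwd", "rev") %in% names(samples)))
  loci <- panel_loci_df(panel)
  min_len <- min(nchar(loci$fwd_primer))
  stats_rows <- list()
  contig_rows <- list()
  for (si in seq_len(nrow(samples))) {
    sm <- samples$sample[si]
    fq_f <- read_fastq_file(samples$fwd[si])
    fq_r <- read_fastq_file(samples$rev[si])
    if (length(fq_f$seq) != length(fq_r$seq)) {
      stop("unequal mate counts for sample ", sm, call. = FALSE)
    }
    n_pairs <- length(fq_f$seq)
    n_qual <- n_merge <- n_unass <- n_ref <- 0L
    kept_locus <- character(0)
    kept_seq <- character(0)
    for (ri in seq_len(n_pairs)) {
      tf <- quality_trim(fq_f$seq[ri], fq_f$qual[[ri]], q_min, window,
                         min_len)
      tr <- quality_trim(fq_r$seq[ri], fq_r$qual[[ri]], q_min, window,
                         min_len)
      if (is.null(tf) || is.null(tr)) { n_qual <- n_qual + 1L; next }
      mg <- merge_pairs(tf$bases, tf$quals, tr$bases, tr$quals,
                        min_overlap, max_mismatch_rate)
      if (is.null(mg)) { n_merge <- n_merge + 1L; next }
      loc <- assign_locus(mg$bases, panel, max_primer_mismatches)
      if (is.na(loc)) { n_unass <- n_unass + 1L; next }
      ref <- loci$reference_prefix[match(loc, loci$locus)]
      if (!reference_filter(mg$bases, ref, min_identity, span)) {
        n_ref <- n_ref + 1L
        next
      }
      kept_locus <- c(kept_locus, loc)
      kept_seq <- c(kept_seq, mg$bases)
    }
    if (length(kept_seq) > 0L) {
      coll <- aggregate(cbind(reads = rep(1L, length(kept_seq))) ~
                          locus + sequence,
                        data = data.frame(locus = kept_locus,
                                          sequence = kept_seq,
                                          stringsAsFactors = FALSE),
                        FUN = sum)
      coll$sample <- sm
      contig_rows[[length(contig_rows) + 1L]] <- coll
    }
    stats_rows[[si]] <- data.frame(
      sample = sm, n_pairs = n_pairs, n_quality_discarded = n_qual,
      n_merge_failed = n_merge, n_unassigned = n_unass,
      n_reference_filtered = n_ref,
      n_counted = n_pairs - n_qual - n_merge - n_unass - n_ref,
      stringsAsFactors = FALSE)
  }
  stats <- do.call(rbind, stats_rows)
  rownames(stats) <- NULL
  if (length(contig_rows) == 0L) {
    counts <- data.frame(sample = character(), locus = character(),
                         allele = character(), reads = integer(),
                         sequence = character())
    return(list(counts = counts, stats = stats))
  }
  counts <- do.call(rbind, contig_rows)
  counts$allele <- catalogue_alleles(counts, panel)
  counts <- counts[order(counts$sample, counts$locus, counts$allele),
                   c("sample", "locus", "allele", "reads", "sequence")]
  rownames(counts) <- NULL
  list(counts = counts, stats = stats)
}

# Stable cross-sample allele identifiers: panel identifiers where the
# sequence is known, fresh "u<k>" identifiers (by decreasing total count)
# otherwise.
catalogue_alleles <- function(counts, panel) {
  ids <- rep(NA_character_, nrow(counts))
  alleles <- panel_alleles_df(panel)
  if (!is.null(alleles)) {
    m <- match(paste(counts$locus, counts$sequence, sep = "\r"),
               paste(alleles$locus, alleles$sequence, sep = "\r"))
    ids <- as.character(alleles$allele[m])
  }
  novel <- is.na(ids)
  if (any(novel)) {
    tot <- aggregate(reads ~ locus + sequence,
                     data = counts[novel, , drop = FALSE], FUN = sum)
    tot <- tot[order(tot$locus, -tot$reads, tot$sequence), ]
    tot$id <- stats::ave(seq_len(nrow(tot)), tot$locus,
                         FUN = seq_along)
    tot$id <- paste0("u", tot$id)
    m <- match(paste(counts$locus[novel], counts$sequence[novel], sep = "\r"),
               paste(tot$locus, tot$sequence, sep = "\r"))
    ids[novel] <- tot$id[m]
  }
  ids
}

panel_loci_df <- function(panel) {
  if (is.data.frame(panel)) return(panel)
  if (is.list(panel) && is.data.frame(panel$loci)) return(panel$loci)
  stop("not a locus panel", call. = FALSE)
}

panel_alleles_df <- function(panel) {
  if (is.list(panel) && !is.data.frame(panel) &&
      is.data.frame(panel$alleles)) {
    return(panel$alleles)
  }
  NULL
}
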