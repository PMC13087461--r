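## Shared fixture: a three-chromosome toy genome with a planted locus on
## "chr13", a matching AAV vector map, the three-primer set whose outer
## product is 2.5 kb on the unedited allele and whose outer x cDNA product
## is 1.6 kb on the knock-in allele, and the WT/NHEJ/HDR allele models.

other_base <- function(b) c(A = "C", C = "A", G = "T", T = "G")[[b]]

make_fixture <- function(seed = 101L) {
  toy <- make_toy_genome(n_chrom = 3L, lengths = c(20000L, 16000L, 16000L),
                         locus_chrom_index = 1L, seed = seed,
                         chrom_names = c("chr13", "chr3", "chr7"))
  genome <- toy$genome
  locus <- toy$locus
  chrom <- genome[["chr13"]]
  cut <- locus$cut_site                      # 10000

  ha5 <- substr(chrom, locus$ha5_interval[1] + 1L, locus$ha5_interval[2])
  ha3 <- substr(chrom, locus$ha3_interval[1] + 1L, locus$ha3_interval[2])
  set.seed(seed + 1L)
  itr <- paste(sample(c("A", "C", "G", "T"), 145L, replace = TRUE),
               collapse = "")
  cdna <- paste(sample(c("A", "C", "G", "T"), 1700L, replace = TRUE),
                collapse = "")
  polya <- paste(sample(c("A", "C", "G", "T"), 200L, replace = TRUE),
                 collapse = "")
  vm <- build_vector_map(ha5 = ha5, cdna = cdna, polya = polya, ha3 = ha3,
                         itr = itr)

  ## outer primers 5' ends at 8800 and 11299 -> 2500 bp WT product;
  ## cDNA primer 5' end at HDR-allele coordinate 10399 -> 1600 bp product
  p_out5 <- substr(chrom, 8801L, 8820L)
  p_out3 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(chrom, 11281L, 11300L))))
  p_cdna <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(cdna, 381L, 400L))))
  primers <- primer_set(p_out5, p_out3, p_cdna)

  ## two PAM-proximal silent mutations (protospacer offsets 14 and 16)
  silent <- lapply(c(14L, 16L), function(k) {
    cur <- substr(locus$protospacer, k + 1L, k + 1L)
    c(k, other_base(cur))
  })
  wt <- build_wt_allele(locus, genome)
  hdr <- build_hdr_allele(locus, genome, vm, silent_mutations = silent)
  nhej <- build_nhej_allele(locus, genome,
                            list(position = cut,
                                 ref_span = substr(chrom, cut + 1L, cut + 3L),
                                 alt_span = ""))

  list(genome = genome, locus = locus, vm = vm, primers = primers,
       alleles = list(WT = wt, NHEJ = nhej, HDR = hdr),
       silent_offsets = c(14L, 16L))
}

## cached: fixture construction is deterministic, reuse across test files
fixture_cache <- new.env(parent = emptyenv())
get_fixture <- function(seed = 101L) {
  key <- as.character(seed)
  if (is.null(fixture_cache[[key]])) fixture_cache[[key]] <- make_fixture(seed)
  fixture_cache[[key]]
}

## per-allele amplicon sequences under the three-primer assay (the products
## a gel would show), via in-silico PCR on each allele
fixture_amplicons <- function(fx) {
  pr <- lapply(fx$alleles, function(a) {
    insilico_pcr(a$sequence, fx$primers)
  })
  list(WT = substr(fx$alleles$WT$sequence, pr$WT$start[1] + 1L, pr$WT$end[1]),
       NHEJ = substr(fx$alleles$NHEJ$sequence, pr$NHEJ$start[1] + 1L,
                     pr$NHEJ$end[1]),
       HDR = substr(fx$alleles$HDR$sequence, pr$HDR$start[1] + 1L,
                    pr$HDR$end[1]))
}

## default population with the two random integrations used in caller tests
fixture_population <- function(vm, episome = 0) {
  vlen <- nchar(vm$sequence)
  cell_population_spec(
    fractions = c(WT = 0.4, NHEJ = 0.4, HDR = 0.2),
    episome_copies_per_genome = episome,
    random_integrations = list(
      list(chrom = "chr3", position = 5000L,
           vector_subinterval = c(vlen - 645L, vlen), orientation = "+"),
      list(chrom = "chr7", position = 8000L,
           vector_subinterval = c(vlen - 645L, vlen), orientation = "-")))
}

## ---- independent oracles --------------------------------------------------

## base-walking CIGAR mapper: walks the CIGAR one operation at a time,
## collecting which stored-orientation read positions are aligned, then
## flips to the original read orientation for minus-strand records
oracle_cigar_intervals <- function(cigar, ref_start, strand, read_length) {
  nums <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  q <- 0L; r <- ref_start
  q_aligned <- integer(0)
  for (i in seq_along(ops)) {
    n <- nums[i]
    switch(ops[i],
           "M" = , "=" = , "X" = {
             q_aligned <- c(q_aligned, q:(q + n - 1L)); q <- q + n; r <- r + n
           },
           "I" = { q <- q + n },
           "S" = , "H" = { q <- q + n },
           "D" = , "N" = { r <- r + n })
  }
  stopifnot(q == read_length)
  lo <- min(q_aligned); hi <- max(q_aligned) + 1L
  if (strand == "-") {
    c(read_length - hi, read_length - lo)
  } else c(lo, hi)
}

## brute-force single-linkage clustering: grow components over the full
## pairwise distance graph
oracle_single_linkage <- function(coords, merge_distance) {
  n <- length(coords)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (abs(coords[i] - coords[j]) <= merge_distance &&
            comp[i] != comp[j]) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  comp
}

## brute-force off-target scan: slide a 23-nt window over both strands
oracle_offtarget_scan <- function(genome, guide, max_mm) {
  rc <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(x)))
  hits <- list()
  for (chrom in names(genome)) {
    seq <- genome[[chrom]]
    L <- nchar(seq)
    for (s in 0:(L - 23L)) {
      w <- substr(seq, s + 1L, s + 23L)
      p20 <- substr(w, 1L, 20L)
      if (substr(w, 22L, 23L) == "GG") {
        mm <- sum(strsplit(p20, "")[[1]] != strsplit(guide, "")[[1]])
        if (mm <= max_mm) {
          hits[[length(hits) + 1L]] <- data.frame(
            chrom = chrom, start = s, strand = "+", n_mismatches = mm)
        }
      }
      if (substr(w, 1L, 2L) == "CC") {
        g <- rc(substr(w, 4L, 23L))
        mm <- sum(strsplit(g, "")[[1]] != strsplit(guide, "")[[1]])
        if (mm <= max_mm) {
          hits[[length(hits) + 1L]] <- data.frame(
            chrom = chrom, start = s + 3L, strand = "-", n_mismatches = mm)
        }
      }
    }
  }
  out <- do.call(rbind, hits)
  out[order(out$n_mismatches, out$chrom, out$start), , drop = FALSE]
}

## unbanded global affine-gap alignment score via Biostrings (independent
## dynamic-programming implementation; gap of length k costs
## gapOpening + k * gapExtension)
oracle_align_score <- function(read, ref, match = 2, mismatch = -4,
                               gap_open = -6, gap_extend = -1) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  Biostrings::pairwiseAlignment(
    pattern = read, subject = ref, type = "global",
    substitutionMatrix = mat, gapOpening = -gap_open,
    gapExtension = -gap_extend, scoreOnly = TRUE)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
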