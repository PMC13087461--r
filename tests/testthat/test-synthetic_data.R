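test_that("toy genome is deterministic with a retrievable planted locus", {
  g1 <- make_toy_genome(2L, c(20000L, 12000L), 1L, seed = 3L)
  g2 <- make_toy_genome(2L, c(20000L, 12000L), 1L, seed = 3L)
  expect_identical(g1$genome, g2$genome)
  ## byte-equal FASTA
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(g1$genome, f1); write_fasta(g2$genome, f2)
  expect_identical(readLines(f1), readLines(f2))
  ## planted protospacer+PAM at the recorded coordinates
  loc <- g1$locus
  site <- vectortrace:::locus_site_sequence(loc, g1$genome)
  expect_identical(substr(site, 1, 20), loc$protospacer)
  expect_identical(substr(site, 22, 23), "GG")
  ## locus must fit
  expect_error(make_toy_genome(1L, c(5000L), 1L, seed = 1L), "size error")
})

test_that("toy genome base composition is uniform", {
  g <- make_toy_genome(1L, c(100000L), 1L, seed = 9L)
  gc <- Biostrings::letterFrequency(
    Biostrings::DNAString(g$genome[[1]]), "GC", as.prob = TRUE)
  expect_gte(gc, 0.47)
  expect_lte(gc, 0.53)
})

test_that("fragmentation tiles the molecule with near-target mean length", {
  mol <- make_toy_genome(1L, c(1000000L), 1L, seed = 2L)$genome[[1]]
  fr <- fragment_genome(mol, mean_len = 10000, seed = 4L)
  expect_identical(paste(fr$seq, collapse = ""), mol)
  expect_equal(fr$start[1], 0L)
  expect_equal(fr$end[nrow(fr)], nchar(mol))
  expect_true(all(fr$start[-1] == fr$end[-nrow(fr)]))
  expect_gte(nrow(fr), 50L)
  expect_lt(abs(mean(fr$end - fr$start) - 10000) / 10000, 0.2)
})

test_that("a molecule shorter than the mean stays whole at the Poisson rate", {
  mol <- strrep("ACGT", 500)   # 2 kb
  whole <- vapply(1:200, function(s) {
    nrow(fragment_genome(mol, mean_len = 10000, seed = s)) == 1L
  }, TRUE)
  p_expected <- exp(-2000 / 10000)      # no breakpoint in L bases
  se <- sqrt(p_expected * (1 - p_expected) / 200)
  expect_lt(abs(mean(whole) - p_expected), 4 * se)
})

test_that("Cas9 enrichment retains guide-overlapping fragments preferentially", {
  mol <- make_toy_genome(1L, c(200000L), 1L, seed = 6L)$genome[[1]]
  fr <- fragment_genome(mol, mean_len = 4000, seed = 7L)
  guide_sites <- seq(10000L, 30000L, by = 2000L)   # ~10% of the molecule
  keep <- cas9_enrich(fr, guide_sites, capture_bias = 20, seed = 8L)
  expect_gt(mean(keep$guide_overlap), 0.5)
  ## pieces split exactly at the recorded cut coordinates
  cut_ends <- keep$end[keep$cut_end]
  expect_true(all(cut_ends %in% guide_sites))
  ## no enrichment limit: retention independent of overlap (chi-squared)
  keep1 <- cas9_enrich(fr, guide_sites, capture_bias = 1, seed = 9L)
  overlaps <- vapply(seq_len(nrow(fr)), function(i) {
    any(guide_sites > fr$start[i] & guide_sites < fr$end[i])
  }, TRUE)
  ## a fragment was retained if any retained piece falls inside it
  retained <- vapply(seq_len(nrow(fr)), function(i) {
    any(keep1$start >= fr$start[i] & keep1$end <= fr$end[i])
  }, TRUE)
  tab <- table(overlaps, retained)
  if (all(dim(tab) == c(2, 2))) {
    expect_gt(suppressWarnings(chisq.test(tab)$p.value), 0.01)
  }
})

test_that("noise-free long reads are exact substrings with consistent truth", {
  fx <- get_fixture()
  pop <- fixture_population(fx$vm)
  sim <- simulate_long_reads(pop, fx$genome, fx$vm, fx$locus,
                             err = error_model(0, 0, 0), n_reads = 60L,
                             seed = 10L, read_len_mean = 4000)
  contigs <- sim$contigs
  for (id in names(sim$reads)) {
    segs <- sim$truth_segments[sim$truth_segments$read_id == id, ]
    read <- sim$reads[[id]]
    ## truth read intervals partition the read
    expect_equal(segs$read_start[1], 0L)
    expect_equal(segs$read_end[nrow(segs)], nchar(read))
    if (nrow(segs) > 1) {
      expect_true(all(segs$read_start[-1] == segs$read_end[-nrow(segs)]))
    }
    ## each piece is the (possibly reverse-complemented) reference slice
    for (i in seq_len(nrow(segs))) {
      piece <- substr(read, segs$read_start[i] + 1L, segs$read_end[i])
      refp <- substr(contigs[[segs$reference[i]]], segs$ref_start[i] + 1L,
                     segs$ref_end[i])
      if (segs$strand[i] == "-") {
        refp <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(refp)))
      }
      expect_identical(piece, refp)
    }
  }
})

test_that("long-read generation is byte-deterministic per seed", {
  fx <- get_fixture()
  pop <- fixture_population(fx$vm)
  s1 <- simulate_long_reads(pop, fx$genome, fx$vm, fx$locus, n_reads = 30L,
                            seed = 12L)
  s2 <- simulate_long_reads(pop, fx$genome, fx$vm, fx$locus, n_reads = 30L,
                            seed = 12L)
  f1 <- withr::local_tempfile(fileext = ".sam")
  f2 <- withr::local_tempfile(fileext = ".sam")
  write_sim_sam(s1, f1); write_sim_sam(s2, f2)
  expect_identical(readLines(f1), readLines(f2))
  q1 <- withr::local_tempfile(fileext = ".fq")
  q2 <- withr::local_tempfile(fileext = ".fq")
  write_fastq(s1$reads, q1); write_fastq(s2$reads, q2)
  expect_identical(readLines(q1), readLines(q2))
})

test_that("substitution load matches the stated error rate", {
  fx <- get_fixture()
  pop <- cell_population_spec(c(WT = 1, NHEJ = 0, HDR = 0))
  err <- error_model(sub_rate = 0.02, ins_rate = 0, del_rate = 0)
  sim <- simulate_long_reads(pop, fx$genome, fx$vm, fx$locus, err = err,
                             n_reads = 40L, seed = 13L,
                             read_len_mean = 4000)
  n_sub <- 0L; n_base <- 0L
  for (id in names(sim$reads)) {
    segs <- sim$truth_segments[sim$truth_segments$read_id == id, ]
    read <- sim$reads[[id]]
    for (i in seq_len(nrow(segs))) {
      piece <- substr(read, segs$read_start[i] + 1L, segs$read_end[i])
      refp <- substr(sim$contigs[[segs$reference[i]]],
                     segs$ref_start[i] + 1L, segs$ref_end[i])
      if (segs$strand[i] == "-") {
        refp <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(refp)))
      }
      n_sub <- n_sub + sum(strsplit(piece, "")[[1]] != strsplit(refp, "")[[1]])
      n_base <- n_base + nchar(piece)
    }
  }
  p_hat <- n_sub / n_base
  expect_lt(abs(p_hat - 0.02), 3 * sqrt(0.02 * 0.98 / n_base))
})

test_that("episomal molecules yield vector-only truth segments", {
  fx <- get_fixture()
  pop <- cell_population_spec(c(WT = 1, NHEJ = 0, HDR = 0),
                              episome_copies_per_genome = 50)
  sim <- simulate_long_reads(pop, fx$genome, fx$vm, fx$locus,
                             err = error_model(0, 0, 0), n_reads = 50L,
                             seed = 14L, read_len_mean = 3000)
  epi_reads <- unique(sim$truth_segments$read_id[
    sim$truth_segments$reference == "pAAV" &
      !sim$truth_segments$read_id %in%
        sim$truth_junctions$read_id])
  expect_gt(length(epi_reads), 0L)
  for (id in epi_reads) {
    segs <- sim$truth_segments[sim$truth_segments$read_id == id, ]
    if (all(segs$reference == "pAAV")) {
      expect_equal(nrow(segs), 1L)
    }
  }
  ## and no junction truth is attributed to episome reads
  expect_false(any(sim$truth_junctions$read_id %in% epi_reads))
})

test_that("FASTQ output round-trips reads and ids", {
  reads <- setNames(c("ACGTACGT", "GGTTAACC"), c("r1", "r2"))
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, fq)
  back <- read_fastq(fq)
  expect_identical(back, reads)
  lines <- readLines(fq)
  expect_equal(lines[3], "+")
  expect_equal(nchar(lines[4]), 8L)       # constant Q20 qualities
})

test_that("amplicon pools respect weights, labels and degenerate inputs", {
  fx <- get_fixture()
  amps <- fixture_amplicons(fx)
  ## exact reads in the no-error, single-allele limit
  s <- simulate_amplicon_reads(amps["WT"], c(WT = 1),
                               err = error_model(0, 0, 0), n_reads = 20L,
                               seed = 15L)
  expect_true(all(s$reads == amps$WT))
  ## binomial recovery of a 40% NHEJ weight
  s2 <- simulate_amplicon_reads(amps[c("WT", "NHEJ")],
                                c(WT = 0.6, NHEJ = 0.4), n_reads = 10000L,
                                seed = 16L)
  f_nhej <- mean(s2$labels == "NHEJ")
  expect_lt(abs(f_nhej - 0.4), 3 * sqrt(0.4 * 0.6 / 10000))
  ## zero reads -> empty, no error
  s3 <- simulate_amplicon_reads(amps["WT"], c(WT = 1), n_reads = 0L)
  expect_length(s3$reads, 0L)
  ## weight validation
  expect_error(simulate_amplicon_reads(amps[c("WT", "NHEJ")],
                                       c(WT = 0.6, NHEJ = 0.6)),
               "sum to 1")
  expect_error(simulate_amplicon_reads(amps["WT"], c(WT = 1),
                                       region = c(5, 5)),
               "region error")
})
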