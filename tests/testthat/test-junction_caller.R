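test_that("SA tag parsing maps fields per the SAM spec", {
  st <- parse_sa_tag("chr3,1000,+,500S4500M,60,12;")
  expect_equal(nrow(st), 1L)
  expect_equal(st$reference, "chr3")
  expect_equal(st$ref_start, 999L)
  expect_equal(st$strand, "+")
  expect_equal(st$cigar, "500S4500M")
  expect_equal(st$mapq, 60L)
  expect_equal(nrow(parse_sa_tag("")), 0L)
  two <- parse_sa_tag("chr3,1000,+,500S4500M,60,12;pAAV,1,-,100M400S,30,2;")
  expect_equal(two$reference, c("chr3", "pAAV"))
  expect_error(parse_sa_tag("chr3,0,+,4500M,60,12;"), "pos must be")
  expect_error(parse_sa_tag("chr3,10,+,4500M,60;"), "6 comma-separated")
  expect_error(parse_sa_tag("chr3,10,*,4500M,60,12;"), "strand")
})

test_that("cigar_intervals matches the clip arithmetic contract", {
  iv <- cigar_intervals("3000M3000S", 499L, "+", 6000L)
  expect_equal(iv$read_interval, c(0L, 3000L))
  expect_equal(iv$ref_interval, c(499L, 3499L))
  iv <- cigar_intervals("3000S3000M", 19999L, "+", 6000L)
  expect_equal(iv$read_interval, c(3000L, 6000L))
  expect_equal(iv$ref_interval, c(19999L, 22999L))
  iv <- cigar_intervals("1000S2000M", 0L, "-", 3000L)
  expect_equal(iv$read_interval, c(0L, 2000L))
  expect_error(cigar_intervals("3000M", 0L, "+", 2999L), "inconsistent")
})

test_that("cigar_intervals equals a base-walking oracle on random CIGARs", {
  set.seed(42)
  for (case in 1:60) {
    ## interior ops bracketed by matches, as real alignments are
    n_mid <- sample(0:6, 1)
    inner <- c("M", sample(c("M", "I", "D"), n_mid, replace = TRUE), "M")
    lens <- sample(1:500, length(inner), replace = TRUE)
    cigar <- paste0(paste0(lens, inner, collapse = ""))
    lead <- sample(0:300, 1); trail <- sample(0:300, 1)
    cigar <- paste0(if (lead) paste0(lead, "S") else "", cigar,
                    if (trail) paste0(trail, "S") else "")
    rl <- sum(lens[inner %in% c("M", "I")]) + lead + trail
    strand <- sample(c("+", "-"), 1)
    rs <- sample(0:10000, 1)
    got <- cigar_intervals(cigar, rs, strand, rl)
    expect_equal(got$read_interval,
                 oracle_cigar_intervals(cigar, rs, strand, rl),
                 info = paste(cigar, strand))
  }
})

test_that("chimeric segment extraction sorts by read offset and counts SA", {
  rec <- list(reference = "pAAV", ref_start = 499L, strand = "+",
              cigar = "3000M3000S", mapq = 60L,
              sa = "chr13,20000,+,3000S3000M,60,0;")
  segs <- extract_chimeric_segments(rec, 6000L)
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$reference, c("pAAV", "chr13"))
  expect_equal(segs$read_start, c(0L, 3000L))
  expect_false(segs$is_supplementary[1])
  ## no SA -> single segment
  rec$sa <- NA_character_
  expect_equal(nrow(extract_chimeric_segments(rec, 6000L)), 1L)
  ## 3 SA entries -> 4 segments
  rec$sa <- paste0("chr13,20000,+,3000S1000M2000S,60,0;",
                   "chr3,1,+,4000S1000M1000S,60,0;",
                   "chr7,1,+,5000S1000M,60,0;")
  expect_equal(nrow(extract_chimeric_segments(rec, 6000L)), 4L)
  ## heavy overlap on the read -> ambiguous, skipped with warning
  rec$sa <- "chr13,20000,+,2000S4000M,60,0;"
  expect_warning(out <- extract_chimeric_segments(rec, 6000L), "ambiguous")
  expect_null(out)
})

test_that("junction coordinates face the breakpoint on both references", {
  fx <- get_fixture()
  segs <- data.frame(
    reference = c("pAAV", "chr13"),
    ref_start = c(499L, 19999L), ref_end = c(3499L, 22999L),
    read_start = c(0L, 3000L), read_end = c(3000L, 6000L),
    strand = "+", cigar = NA, mapq = 60L, is_supplementary = c(FALSE, TRUE),
    stringsAsFactors = FALSE)
  ev <- call_junctions(segs, "pAAV", fx$vm)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$vector_coord, 3499L)
  expect_equal(ev$host_chrom, "chr13")
  expect_equal(ev$host_coord, 19999L)
  expect_equal(ev$orientation, "vector->host")
  expect_equal(ev$read_gap, 0L)
  ## vector coordinate 3499 falls in the HA3 segment of the 4190-bp fixture
  expect_equal(ev$vector_segment,
               vectortrace:::vector_segment_at(fx$vm, 3498L))
  ## host-host pair yields nothing
  segs2 <- segs; segs2$reference <- c("chr3", "chr13")
  expect_equal(nrow(call_junctions(segs2, "pAAV", fx$vm)), 0L)
  ## vector-only read (episome) yields nothing
  segs3 <- segs; segs3$reference <- c("pAAV", "pAAV")
  expect_equal(nrow(call_junctions(segs3, "pAAV", fx$vm)), 0L)
  ## mapq and length filters
  segs4 <- segs; segs4$mapq <- c(60L, 10L)
  expect_equal(nrow(call_junctions(segs4, "pAAV", fx$vm)), 0L)
  expect_equal(nrow(call_junctions(segs, "pAAV", fx$vm,
                                   min_segment_len = 3500L)), 0L)
})

test_that("minus-strand junction coordinates mirror correctly", {
  fx <- get_fixture()
  ## read: host piece then vector piece, both minus strand; junction faces
  ## the host segment's ref start and the vector segment's ref end
  segs <- data.frame(
    reference = c("chr13", "pAAV"),
    ref_start = c(5000L, 1000L), ref_end = c(7000L, 2000L),
    read_start = c(0L, 2000L), read_end = c(2000L, 3000L),
    strand = "-", cigar = NA, mapq = 60L, is_supplementary = FALSE,
    stringsAsFactors = FALSE)
  ev <- call_junctions(segs, "pAAV", fx$vm)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$host_coord, 5000L)
  expect_equal(ev$vector_coord, 2000L)
  expect_equal(ev$orientation, "host->vector")
})

test_that("single-linkage clustering matches a brute-force oracle", {
  ev <- data.frame(read_id = paste0("r", c(1, 2, 3, 3)),
                   host_chrom = "chr13",
                   host_coord = c(19999L, 19999L, 19999L, 20010L),
                   stringsAsFactors = FALSE)
  sites <- cluster_sites(ev, merge_distance = 50L)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$representative_coord, 19999L)
  expect_equal(sites$support, 3L)          # distinct reads
  ## two separated clusters
  ev2 <- data.frame(read_id = c("a", "b"), host_chrom = "chrX",
                    host_coord = c(100L, 500L))
  expect_equal(nrow(cluster_sites(ev2, 50L)), 2L)
  expect_equal(nrow(cluster_sites(ev2[0, ], 50L)), 0L)
  ## randomized comparison with the all-pairs oracle
  set.seed(11)
  for (case in 1:25) {
    coords <- sample(0:2000, sample(2:40, 1), replace = TRUE)
    d <- sample(c(0L, 10L, 50L, 200L), 1)
    ev3 <- data.frame(read_id = paste0("r", seq_along(coords)),
                      host_chrom = "chr1", host_coord = coords)
    got <- cluster_sites(ev3, d)
    comp <- oracle_single_linkage(coords, d)
    expect_equal(nrow(got), length(unique(comp)), info = paste(d))
    ## per-cluster membership sizes agree
    expect_equal(sort(got$n_events), sort(unname(table(comp))),
                 ignore_attr = TRUE)
  }
})

test_that("site classification separates targeted locus from other sites", {
  fx <- get_fixture()
  ev <- data.frame(read_id = c("r1", "r2"),
                   host_chrom = c("chr13", "chr3"),
                   host_coord = c(fx$locus$cut_site, 5000L))
  sites <- cluster_sites(ev, 50L)
  ot <- data.frame(chrom = "chr3", cut_site = 1000000L)
  cls <- classify_sites(sites, fx$locus, targeted_window = 1000L,
                        predicted_offtargets = ot)
  expect_equal(cls$classification[cls$host_chrom == "chr13"], "targeted")
  expect_equal(cls$classification[cls$host_chrom == "chr3"], "other")
  expect_equal(cls$nearest_offtarget_distance[cls$host_chrom == "chr3"],
               995000)
  expect_true(is.na(cls$nearest_offtarget_distance[cls$host_chrom == "chr13"]))
  ## empty predicted list -> all distances NA
  cls2 <- classify_sites(sites, fx$locus)
  expect_true(all(is.na(cls2$nearest_offtarget_distance)))
})

test_that("SAM writing and re-reading preserves the junction structure", {
  fx <- get_fixture()
  pop <- fixture_population(fx$vm)
  sim <- simulate_long_reads(pop, fx$genome, fx$vm, fx$locus,
                             err = error_model(0, 0, 0), n_reads = 120L,
                             seed = 5L, read_len_mean = 5000,
                             read_len_sd = 1000)
  path <- withr::local_tempfile(fileext = ".sam")
  write_sim_sam(sim, path)
  records <- read_sam(path)
  expect_equal(sort(records$qname), sort(sim$records$qname))
  ev_file <- junctions_from_sam(records, "pAAV", fx$vm)
  ev_mem <- junctions_from_sam(sim$records, "pAAV", fx$vm)
  key <- function(e) sort(paste(e$read_id, e$host_chrom, e$host_coord,
                                e$vector_coord))
  expect_identical(key(ev_file), key(ev_mem))
  expect_gt(nrow(ev_file), 0L)
})
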