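## Truth-annotated synthetic data emulating the study's two sequencing
## experiments: Cas9-enriched long-read libraries over a combined
## host+vector reference (integration detection) and amplicon pools with
## known allele fractions (editing quantification).
##
## Every generator takes an explicit seed and is byte-deterministic for a
## fixed seed. Truth output (segments, junctions, sites) is recorded from
## the molecule models themselves, independently of any caller code.

#' Per-base sequencing error model
#'
#' Substitutions, single-base insertions and single-base deletions are drawn
#' independently per base. Defaults are nanopore-like (~3% total error).
#'
#' @param sub_rate,ins_rate,del_rate per-base probabilities, each in
#'   `[0, 0.2]`
#' @return an `ErrorModel`
#' @export
error_model <- function(sub_rate = 0.02, ins_rate = 0.005, del_rate = 0.005) {
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(rates < 0) || any(rates > 0.2)) {
    stop("error rates must lie in [0, 0.2]", call. = FALSE)
  }
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate), class = "ErrorModel")
}

#' Cell-population specification for the integration assay
#'
#' @param fractions named numeric `c(WT=, NHEJ=, HDR=)`, nonnegative,
#'   summing to 1
#' @param episome_copies_per_genome expected free episomal vector copies per
#'   genome; default 0 mirrors a culture washout that removes residual
#'   episomal AAV
#' @param random_integrations list of non-targeted integration events, each
#'   a list with `chrom`, `position` (0-based host insertion point),
#'   `vector_subinterval` (`c(start, end)` on the vector, 0-based half-open)
#'   and `orientation` (`"+"`/`"-"`)
#' @return a `CellPopulationSpec`
#' @export
cell_population_spec <- function(fractions = c(WT = 0.4, NHEJ = 0.4, HDR = 0.2),
                                 episome_copies_per_genome = 0,
                                 random_integrations = list()) {
  if (!all(c("WT", "NHEJ", "HDR") %in% names(fractions))) {
    stop("fractions must name WT, NHEJ and HDR", call. = FALSE)
  }
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must be nonnegative and sum to 1", call. = FALSE)
  }
  stopifnot(episome_copies_per_genome >= 0)
  structure(list(fractions = fractions,
                 episome_copies_per_genome = episome_copies_per_genome,
                 random_integrations = random_integrations),
            class = "CellPopulationSpec")
}

#' Generate a toy genome with a planted target locus
#'
#' Uniform-random contigs; on the locus chromosome a 20-nt protospacer
#' followed by an AGG PAM is planted at the recorded position, with 1-kb
#' homology-arm intervals flanking the cut site (3 bp 5' of the PAM).
#'
#' @param n_chrom number of contigs
#' @param lengths integer vector of contig lengths; the locus chromosome
#'   must be at least 10 kb
#' @param locus_chrom_index 1-based index of the chromosome carrying the
#'   locus
#' @param seed RNG seed
#' @param chrom_names optional contig names (default `chr1..chrN`)
#' @param cut_at 0-based cut position on the locus chromosome (default:
#'   middle of the contig)
#' @return list with `genome` (named character) and `locus` (`TargetLocus`)
#' @export
make_toy_genome <- function(n_chrom, lengths, locus_chrom_index = 1L,
                            seed = 1L, chrom_names = NULL, cut_at = NULL) {
  stopifnot(length(lengths) == n_chrom,
            locus_chrom_index >= 1L, locus_chrom_index <= n_chrom)
  if (lengths[locus_chrom_index] < 10000L) {
    stop("size error: locus chromosome must be at least 10 kb", call. = FALSE)
  }
  if (is.null(chrom_names)) chrom_names <- paste0("chr", seq_len(n_chrom))
  with_seed(seed, {
    genome <- setNames(vapply(lengths, random_dna, ""), chrom_names)
    chrom <- chrom_names[locus_chrom_index]
    L <- lengths[locus_chrom_index]
    cut <- if (is.null(cut_at)) L %/% 2L else as.integer(cut_at)
    if (cut - 1100L < 0L || cut + 1100L > L) {
      stop("size error: locus does not fit on the chromosome", call. = FALSE)
    }
    guide <- random_dna(20L)
    site <- paste0(guide, "AGG")
    s <- substr(genome[[chrom]], 1L, cut - 17L)
    e <- substr(genome[[chrom]], cut + 6L + 1L, L)
    genome[[chrom]] <- paste0(s, site, e)
    locus <- target_locus(chrom = chrom, strand = "+", cut_site = cut,
                          protospacer = guide, pam = "AGG",
                          ha5_interval = c(cut - 1000L, cut),
                          ha3_interval = c(cut, cut + 1000L))
    list(genome = genome, locus = locus)
  })
}

#' Fragment a molecule by a Poisson breakage process
#'
#' Breakpoints are spaced exponentially with mean `mean_len` (rate
#' `1/mean_len`), emulating mechanical shearing to a target fragment size;
#' the fragments tile the molecule exactly.
#'
#' @param molecule DNA string
#' @param mean_len target mean fragment length (>= 1000 bp)
#' @param seed RNG seed
#' @return data.frame `start`, `end` (0-based half-open on the molecule),
#'   `seq`
#' @export
fragment_genome <- function(molecule, mean_len, seed = 1L) {
  stopifnot(mean_len >= 1000)
  L <- nchar(molecule)
  with_seed(seed, {
    cuts <- integer(0)
    pos <- 0
    repeat {
      pos <- pos + rexp(1L, rate = 1 / mean_len)
      if (pos >= L) break
      cuts <- c(cuts, as.integer(floor(pos)))
    }
    cuts <- unique(cuts[cuts > 0L & cuts < L])
    bounds <- c(0L, cuts, L)
    data.frame(start = bounds[-length(bounds)], end = bounds[-1L],
               seq = substring(molecule, bounds[-length(bounds)] + 1L,
                               bounds[-1L]),
               stringsAsFactors = FALSE)
  })
}

#' Cas9 in-vitro enrichment of fragments at guide sites
#'
#' Fragments overlapping a guide site are cleaved at the site and each
#' resulting piece is retained with probability `p_cut`; fragments without a
#' guide site are retained with probability `p_cut / capture_bias`,
#' modelling preferential adapter ligation at fresh Cas9 cut ends.
#'
#' @param fragments data.frame from [fragment_genome()] (`start`, `end`,
#'   `seq` in molecule coordinates)
#' @param guide_sites 0-based cut positions on the molecule
#' @param capture_bias enrichment factor (>= 1)
#' @param p_cut retention probability for guide-overlapping pieces
#' @param seed RNG seed
#' @return retained fragments with added columns `guide_overlap`,
#'   `cut_start`, `cut_end`
#' @export
cas9_enrich <- function(fragments, guide_sites, capture_bias = 20,
                        p_cut = 0.9, seed = 1L) {
  stopifnot(capture_bias >= 1, p_cut >= 0, p_cut <= 1)
  with_seed(seed, {
    pieces <- list()
    for (i in seq_len(nrow(fragments))) {
      fr <- fragments[i, ]
      sites <- sort(guide_sites[guide_sites > fr$start & guide_sites < fr$end])
      if (length(sites) == 0L) {
        if (runif(1L) < p_cut / capture_bias) {
          fr$guide_overlap <- FALSE; fr$cut_start <- FALSE; fr$cut_end <- FALSE
          pieces[[length(pieces) + 1L]] <- fr
        }
        next
      }
      bounds <- c(fr$start, sites, fr$end)
      for (k in seq_len(length(bounds) - 1L)) {
        if (runif(1L) >= p_cut) next
        st <- bounds[k]; en <- bounds[k + 1L]
        pieces[[length(pieces) + 1L]] <- data.frame(
          start = st, end = en,
          seq = substr(fr$seq, st - fr$start + 1L, en - fr$start),
          guide_overlap = TRUE, cut_start = st %in% sites,
          cut_end = en %in% sites, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, pieces)
    if (is.null(out)) {
      out <- data.frame(start = integer(), end = integer(), seq = character(),
                        guide_overlap = logical(), cut_start = logical(),
                        cut_end = logical(), stringsAsFactors = FALSE)
    }
    rownames(out) <- NULL
    out
  })
}

## ---- internal: molecule models --------------------------------------------

## a molecule is a list(name, segments) where segments is a data.frame
## (reference, ref_start, ref_end, strand) in molecule order; sequence and
## molecule coordinates are derived. Junctions between host and vector
## segments are recorded with the facing coordinates on both references.
build_molecule <- function(name, segments, contigs) {
  segs <- segments
  segs$len <- segs$ref_end - segs$ref_start
  segs$mol_end <- cumsum(segs$len)
  segs$mol_start <- segs$mol_end - segs$len
  seq <- paste(vapply(seq_len(nrow(segs)), function(i) {
    s <- substr(contigs[[segs$reference[i]]], segs$ref_start[i] + 1L,
                segs$ref_end[i])
    if (segs$strand[i] == "-") revcomp(s) else s
  }, ""), collapse = "")
  list(name = name, segments = segs, seq = seq, length = nchar(seq))
}

## facing reference coordinate at a molecule-internal boundary
## side = "left": coordinate of the segment ending at the boundary
boundary_coord <- function(seg, side) {
  right_ref_edge <- (side == "left") == (seg$strand == "+")
  if (right_ref_edge) seg$ref_end else seg$ref_start
}

molecule_junctions <- function(mol, vector_contig) {
  segs <- mol$segments
  out <- list()
  if (nrow(segs) < 2L) return(NULL)
  for (i in seq_len(nrow(segs) - 1L)) {
    a <- segs[i, ]; b <- segs[i + 1L, ]
    a_vec <- a$reference == vector_contig
    b_vec <- b$reference == vector_contig
    if (a_vec == b_vec) next
    host <- if (a_vec) b else a
    vec <- if (a_vec) a else b
    out[[length(out) + 1L]] <- data.frame(
      mol_coord = a$mol_end,
      host_chrom = host$reference,
      host_coord = boundary_coord(host, if (a_vec) "right" else "left"),
      vector_coord = boundary_coord(vec, if (a_vec) "left" else "right"),
      stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else NULL
}

## apply the error model to one sequence piece; returns the mutated piece,
## its CIGAR runs (read order, walking the piece's reference direction) and
## the edit count
mutate_piece <- function(seq, err) {
  L <- nchar(seq)
  if (L == 0L) {
    return(list(seq = "", runs = data.frame(len = integer(), op = character()),
                nerr = 0L))
  }
  if (err$sub_rate == 0 && err$ins_rate == 0 && err$del_rate == 0) {
    return(list(seq = seq,
                runs = data.frame(len = L, op = "M",
                                  stringsAsFactors = FALSE),
                nerr = 0L))
  }
  bases <- strsplit(seq, "")[[1]]
  del <- runif(L) < err$del_rate
  sub <- !del & (runif(L) < err$sub_rate)
  ins <- runif(L) < err$ins_rate
  if (any(sub)) {
    cur <- bases[sub]
    repl <- vapply(cur, function(b) sample(setdiff(DNA_ALPHABET, b), 1L), "")
    bases[sub] <- repl
  }
  ins_base <- character(L)
  if (any(ins)) ins_base[ins] <- sample(DNA_ALPHABET, sum(ins), replace = TRUE)
  out_base <- ifelse(del, "", bases)
  new_seq <- paste(paste0(out_base, ins_base), collapse = "")
  op_per <- ifelse(del, "D", "M")
  ops <- as.vector(rbind(op_per, ifelse(ins, "I", "")))
  ops <- ops[nzchar(ops)]
  r <- rle(ops)
  list(seq = new_seq,
       runs = data.frame(len = r$lengths, op = r$values,
                         stringsAsFactors = FALSE),
       nerr = sum(del) + sum(sub) + sum(ins))
}

runs_to_cigar <- function(runs) {
  if (nrow(runs) == 0L) return("")
  paste0(runs$len, runs$op, collapse = "")
}

## reverse CIGAR runs (for minus-strand SAM records)
rev_runs <- function(runs) runs[rev(seq_len(nrow(runs))), , drop = FALSE]

## ---- long-read simulation -------------------------------------------------

#' Simulate Cas9-enriched long reads over a combined host+vector reference
#'
#' Builds molecule models for the cell population — unedited and
#' NHEJ-carrying copies of the locus chromosome (identical at long-read
#' junction resolution), the HDR knock-in chromosome (cDNA+polyA seamlessly
#' inserted at the cut site), chromosome variants carrying each random
#' integration, free episomal vector molecules — samples reads from them in
#' both orientations, applies the error model, and emits reads together
#' with a truth alignment table (primary record + SA tag per chimeric read)
#' and molecule-level truth junctions and sites.
#'
#' @param population a `CellPopulationSpec`
#' @param genome host genome (named character or `DNAStringSet`)
#' @param vector a `VectorMap`
#' @param locus a `TargetLocus`
#' @param err an `ErrorModel`
#' @param n_reads number of reads
#' @param seed RNG seed
#' @param read_len_mean,read_len_sd,read_len_min read-length distribution
#'   (normal, clipped)
#' @return list: `reads` (named character), `records` (primary-alignment
#'   table as produced by [read_sam()], SA tags encoding chimeric
#'   structure), `truth_segments` (per-read truth), `truth_junctions`
#'   (per-read vector-host junctions), `truth_sites` (molecule-level
#'   data.frame `host_chrom`, `host_coord`, `kind`), `contigs` (the combined
#'   reference contigs)
#' @export
simulate_long_reads <- function(population, genome, vector, locus,
                                err = error_model(), n_reads, seed = 1L,
                                read_len_mean = 6000, read_len_sd = 1500,
                                read_len_min = 300) {
  stopifnot(inherits(population, "CellPopulationSpec"), n_reads >= 0)
  genome <- as_genome(genome)
  combined <- build_combined_reference(genome, vector)
  contigs <- combined$contigs
  vname <- combined$vector_contig_name
  f <- population$fractions

  cdna_iv <- vector$segments[vector$segments$label == "CDNA", ]
  polya_iv <- vector$segments[vector$segments$label == "POLYA", ]
  insert_iv <- c(cdna_iv$start, polya_iv$end)

  host_seg <- function(chrom, s, e) {
    data.frame(reference = chrom, ref_start = s, ref_end = e, strand = "+",
               stringsAsFactors = FALSE)
  }

  mols <- list(); weights <- numeric(0); kinds <- character(0)
  add_mol <- function(m, w, kind) {
    mols[[length(mols) + 1L]] <<- m
    weights <<- c(weights, w)
    kinds <<- c(kinds, kind)
  }

  rand_by_chrom <- split(
    population$random_integrations,
    vapply(population$random_integrations, function(x) x$chrom, ""))

  for (chrom in names(genome)) {
    L <- nchar(genome[[chrom]])
    if (chrom == locus$chrom) {
      ## WT + NHEJ copies (identical at junction resolution)
      add_mol(build_molecule(paste0(chrom, ":WT"), host_seg(chrom, 0L, L),
                             contigs),
              (f[["WT"]] + f[["NHEJ"]]) * L, "host")
      ## HDR knock-in copy
      segs <- rbind(host_seg(chrom, 0L, locus$ha5_interval[2]),
                    data.frame(reference = vname, ref_start = insert_iv[1],
                               ref_end = insert_iv[2], strand = "+",
                               stringsAsFactors = FALSE),
                    host_seg(chrom, locus$ha3_interval[1], L))
      add_mol(build_molecule(paste0(chrom, ":HDR"), segs, contigs),
              f[["HDR"]] * L, "hdr")
    } else if (chrom %in% names(rand_by_chrom)) {
      for (ri in rand_by_chrom[[chrom]]) {
        segs <- rbind(host_seg(chrom, 0L, ri$position),
                      data.frame(reference = vname,
                                 ref_start = ri$vector_subinterval[1],
                                 ref_end = ri$vector_subinterval[2],
                                 strand = ri$orientation,
                                 stringsAsFactors = FALSE),
                      host_seg(chrom, ri$position, L))
        add_mol(build_molecule(paste0(chrom, ":RI"), segs, contigs),
                L, "random_integration")
      }
    } else {
      add_mol(build_molecule(chrom, host_seg(chrom, 0L, L), contigs),
              L, "host")
    }
  }
  if (population$episome_copies_per_genome > 0) {
    vl <- nchar(vector$sequence)
    add_mol(build_molecule("episome",
                           data.frame(reference = vname, ref_start = 0L,
                                      ref_end = vl, strand = "+",
                                      stringsAsFactors = FALSE), contigs),
            population$episome_copies_per_genome * vl, "episome")
  }

  truth_sites <- do.call(rbind, lapply(seq_along(mols), function(i) {
    j <- molecule_junctions(mols[[i]], vname)
    if (is.null(j)) return(NULL)
    data.frame(host_chrom = j$host_chrom, host_coord = j$host_coord,
               kind = kinds[i], stringsAsFactors = FALSE)
  }))
  if (is.null(truth_sites)) {
    truth_sites <- data.frame(host_chrom = character(),
                              host_coord = integer(), kind = character(),
                              stringsAsFactors = FALSE)
  }

  with_seed(seed, {
    reads <- character(n_reads)
    ids <- character(n_reads)
    rec_rows <- vector("list", n_reads)
    seg_rows <- vector("list", n_reads)
    jun_rows <- vector("list", n_reads)
    mol_idx <- if (length(mols)) {
      sample.int(length(mols), n_reads, replace = TRUE, prob = weights)
    } else integer(0)

    for (r in seq_len(n_reads)) {
      mol <- mols[[mol_idx[r]]]
      rl <- round(stats::rnorm(1L, read_len_mean, read_len_sd))
      rl <- max(read_len_min, min(rl, mol$length))
      s <- if (mol$length > rl) sample.int(mol$length - rl + 1L, 1L) - 1L else 0L
      e <- s + rl
      flip <- runif(1L) < 0.5
      id <- sprintf("read%06d", r)

      ## truth pieces: intersect [s, e) with molecule segments
      segs <- mol$segments
      pieces <- list()
      for (i in seq_len(nrow(segs))) {
        a <- max(s, segs$mol_start[i]); b <- min(e, segs$mol_end[i])
        if (a >= b) next
        if (segs$strand[i] == "+") {
          fs <- segs$ref_start[i] + (a - segs$mol_start[i]); fe <- fs + (b - a)
        } else {
          fe <- segs$ref_end[i] - (a - segs$mol_start[i]); fs <- fe - (b - a)
        }
        fs <- as.integer(fs); fe <- as.integer(fe)
        mut <- mutate_piece(substr(mol$seq, a + 1L, b), err)
        pieces[[length(pieces) + 1L]] <- list(
          reference = segs$reference[i], fs = fs, fe = fe,
          strand = segs$strand[i], seq = mut$seq, runs = mut$runs,
          nerr = mut$nerr)
      }
      if (flip) {
        ## reversing the read flips each piece's effective strand; CIGAR runs
        ## are reversed here so that the later "reverse for minus-strand
        ## records" rule always yields reference-forward order
        pieces <- rev(pieces)
        for (i in seq_along(pieces)) {
          pieces[[i]]$seq <- revcomp_or_empty(pieces[[i]]$seq)
          pieces[[i]]$strand <- if (pieces[[i]]$strand == "+") "-" else "+"
          pieces[[i]]$runs <- rev_runs(pieces[[i]]$runs)
        }
      }
      plens <- vapply(pieces, function(p) nchar(p$seq), 0L)
      read_seq <- paste(vapply(pieces, `[[`, "", "seq"), collapse = "")
      rlen <- sum(plens)
      read_ends <- cumsum(plens); read_starts <- read_ends - plens

      seg_df <- data.frame(
        read_id = id,
        reference = vapply(pieces, `[[`, "", "reference"),
        ref_start = as.integer(vapply(pieces, `[[`, 0, "fs")),
        ref_end = as.integer(vapply(pieces, `[[`, 0, "fe")),
        read_start = read_starts, read_end = read_ends,
        strand = vapply(pieces, `[[`, "", "strand"),
        stringsAsFactors = FALSE)

      ## per-record SAM CIGARs: core runs in reference-forward order, with
      ## soft clips for the rest of the read
      sam_cigar <- character(length(pieces))
      for (i in seq_along(pieces)) {
        p <- pieces[[i]]
        core <- if (p$strand == "+") p$runs else rev_runs(p$runs)
        lead <- if (p$strand == "+") read_starts[i] else rlen - read_ends[i]
        trail <- rlen - lead - plens[i]
        sam_cigar[i] <- paste0(if (lead > 0L) paste0(lead, "S") else "",
                               runs_to_cigar(core),
                               if (trail > 0L) paste0(trail, "S") else "")
      }
      sa_entry <- vapply(seq_along(pieces), function(i) {
        p <- pieces[[i]]
        sprintf("%s,%d,%s,%s,%d,%d", p$reference, p$fs + 1L, p$strand,
                sam_cigar[i], 60L, p$nerr)
      }, "")
      primary <- which.max(plens)
      sa_tag <- if (length(pieces) > 1L) {
        paste0(paste(sa_entry[-primary], collapse = ";"), ";")
      } else NA_character_

      rec_rows[[r]] <- data.frame(
        qname = id, reference = pieces[[primary]]$reference,
        ref_start = pieces[[primary]]$fs,
        strand = pieces[[primary]]$strand, cigar = sam_cigar[primary],
        mapq = 60L, sa = sa_tag, read_length = rlen,
        all_cigars = I(list(sam_cigar)), all_sa = I(list(sa_entry)),
        primary_index = primary, stringsAsFactors = FALSE)

      mj <- molecule_junctions(mol, vname)
      if (!is.null(mj)) {
        covered <- mj[mj$mol_coord > s & mj$mol_coord < e, , drop = FALSE]
        if (nrow(covered)) {
          covered$read_id <- id
          jun_rows[[r]] <- covered[, c("read_id", "host_chrom", "host_coord",
                                       "vector_coord")]
        }
      }
      reads[r] <- read_seq
      ids[r] <- id
      seg_rows[[r]] <- seg_df
    }

    names(reads) <- ids
    records <- if (n_reads > 0L) do.call(rbind, rec_rows) else
      read_sam_empty()
    truth_segments <- if (n_reads > 0L) do.call(rbind, seg_rows) else NULL
    truth_junctions <- do.call(rbind, jun_rows)
    if (is.null(truth_junctions)) {
      truth_junctions <- data.frame(read_id = character(),
                                    host_chrom = character(),
                                    host_coord = integer(),
                                    vector_coord = integer(),
                                    stringsAsFactors = FALSE)
    }
    rownames(records) <- NULL
    list(reads = reads, records = records, truth_segments = truth_segments,
         truth_junctions = truth_junctions, truth_sites = truth_sites,
         contigs = contigs, vector_contig_name = vname, seed = seed)
  })
}

revcomp_or_empty <- function(x) if (nzchar(x)) revcomp(x) else x

read_sam_empty <- function() {
  data.frame(qname = character(), reference = character(),
             ref_start = integer(), strand = character(), cigar = character(),
             mapq = integer(), sa = character(), read_length = integer(),
             stringsAsFactors = FALSE)
}

#' Write a simulation's truth alignments as a SAM file
#'
#' Emits a primary record per read plus supplementary records for the other
#' chimeric segments, each carrying an SA:Z tag per the SAM specification
#' (1-based positions). The header records the generator seed.
#'
#' @param sim result of [simulate_long_reads()]
#' @param path output SAM path
#' @return `path`, invisibly
#' @export
write_sim_sam <- function(sim, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(sim$contigs),
                   nchar(sim$contigs)),
           sprintf("@PG\tID:vectortrace\tPN:vectortrace\tCL:seed=%d",
                   sim$seed))
  lines <- character(0)
  recs <- sim$records
  for (r in seq_len(nrow(recs))) {
    segs <- sim$truth_segments[sim$truth_segments$read_id == recs$qname[r], ,
                               drop = FALSE]
    cigs <- recs$all_cigars[[r]]
    sas <- recs$all_sa[[r]]
    primary <- recs$primary_index[r]
    seq <- sim$reads[[recs$qname[r]]]
    for (i in seq_len(nrow(segs))) {
      flag <- 0L
      if (segs$strand[i] == "-") flag <- flag + 16L
      if (i != primary) flag <- flag + 2048L
      others <- sas[-i]
      opt <- if (length(others)) {
        paste0("\tSA:Z:", paste(others, collapse = ";"), ";")
      } else ""
      out_seq <- if (segs$strand[i] == "-") revcomp(seq) else seq
      qual <- strrep("5", nchar(out_seq))
      lines <- c(lines, sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s%s",
                                segs$read_id[i], flag, segs$reference[i],
                                segs$ref_start[i] + 1L, 60L, cigs[i],
                                out_seq, qual, opt))
    }
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Simulate amplicon reads from weighted alleles
#'
#' Reads are drawn from the allele sequences (optionally restricted to a
#' region), sequencing errors applied per the error model, and the true
#' source allele recorded per read.
#'
#' @param alleles named list of `AlleleModel`s or DNA strings
#' @param weights numeric, same names/order as `alleles`, summing to 1
#' @param region optional `c(start, end)` (0-based half-open) applied to each
#'   allele sequence (clamped to its length); `NULL` uses full sequences
#' @param err an `ErrorModel`; the default is short-read/Sanger-like
#'   (substitutions 0.002/base, indels 1e-4/base) since amplicon products
#'   are sequenced on a high-accuracy platform, unlike the nanopore
#'   long-read libraries
#' @param n_reads number of reads (0 allowed)
#' @param seed RNG seed
#' @return list: `reads` (named character), `labels` (true allele per read)
#' @export
simulate_amplicon_reads <- function(alleles, weights, region = NULL,
                                    err = error_model(0.002, 1e-4, 1e-4),
                                    n_reads = 1000L, seed = 1L) {
  stopifnot(length(alleles) == length(weights), n_reads >= 0)
  if (abs(sum(weights) - 1) > 1e-9 || any(weights < 0)) {
    stop("weights must be nonnegative and sum to 1", call. = FALSE)
  }
  seqs <- vapply(alleles, function(a) {
    if (inherits(a, "AlleleModel")) a$sequence else a
  }, "")
  if (!is.null(region)) {
    if (!interval_ok(region) || region[1] == region[2]) {
      stop("region error: empty or invalid region", call. = FALSE)
    }
    seqs <- vapply(seqs, function(s) {
      substr(s, region[1] + 1L, min(region[2], nchar(s)))
    }, "")
  }
  if (n_reads == 0L) {
    return(list(reads = setNames(character(0), character(0)),
                labels = character(0)))
  }
  with_seed(seed, {
    lab <- sample(names(alleles), n_reads, replace = TRUE, prob = weights)
    reads <- vapply(lab, function(l) mutate_piece(seqs[[l]], err)$seq, "")
    names(reads) <- sprintf("amp%06d_%s", seq_len(n_reads), lab)
    list(reads = reads, labels = lab)
  })
}
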