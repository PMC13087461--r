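## Candidate off-target enumeration by mismatch scan (NGG PAM) and per-site
## indel background screening from amplicon reads.

count_mismatches <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Enumerate candidate off-target sites of a guide
#'
#' Scans both strands of the genome for NGG-adjacent 20-mers within
#' `max_mismatches` Hamming distance of the protospacer (mismatches counted
#' in the protospacer only; the PAM must match NGG exactly). The on-target
#' site is excluded when `locus` is given. Output is sorted by
#' `(n_mismatches, chrom, start)` and deterministic.
#'
#' @param genome named character vector or `DNAStringSet`
#' @param protospacer 20-nt guide sequence
#' @param max_mismatches Hamming threshold (<= 6)
#' @param locus optional `TargetLocus`; its cut site is excluded
#' @param features optional data.frame (`chrom`, `start`, `end`, `name`,
#'   0-based half-open) used to annotate sites; unmatched sites are
#'   `"unannotated"`
#' @return data.frame of `OffTargetSite`s: `chrom`, `start` (0-based start
#'   of the 20-mer on the plus strand), `strand`, `site_sequence`
#'   (protospacer+PAM on the guide strand), `n_mismatches`, `cut_site`
#'   (0-based cut boundary), `annotation`
#' @export
enumerate_offtargets <- function(genome, protospacer, max_mismatches = 4L,
                                 locus = NULL, features = NULL) {
  if (grepl("[^ACGT]", protospacer)) {
    stop("invalid-guide: protospacer must be ACGT only", call. = FALSE)
  }
  stopifnot(nchar(protospacer) == 20L, max_mismatches <= 6L)
  genome <- as_genome(genome)
  rows <- list()
  for (chrom in names(genome)) {
    seq <- genome[[chrom]]
    subject <- Biostrings::DNAString(seq)
    L <- nchar(seq)
    ## plus strand: protospacer then NGG
    m <- Biostrings::matchPattern(protospacer, subject,
                                  max.mismatch = max_mismatches,
                                  with.indels = FALSE)
    for (i in seq_along(m)) {
      st0 <- BiocGenerics::start(m)[i] - 1L
      if (st0 + 23L > L) next
      pam <- substr(seq, st0 + 21L, st0 + 23L)
      if (substr(pam, 2L, 3L) != "GG") next
      hit20 <- substr(seq, st0 + 1L, st0 + 20L)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = st0, strand = "+",
        site_sequence = paste0(hit20, pam),
        n_mismatches = count_mismatches(hit20, protospacer),
        cut_site = st0 + 17L, stringsAsFactors = FALSE)
    }
    ## minus strand: CCN then revcomp(protospacer) on the plus strand
    m <- Biostrings::matchPattern(revcomp(protospacer), subject,
                                  max.mismatch = max_mismatches,
                                  with.indels = FALSE)
    for (i in seq_along(m)) {
      st0 <- BiocGenerics::start(m)[i] - 1L
      if (st0 - 3L < 0L) next
      if (substr(seq, st0 - 2L, st0 - 1L) != "CC") next
      hit20 <- revcomp(substr(seq, st0 + 1L, st0 + 20L))
      pam <- revcomp(substr(seq, st0 - 2L, st0))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = st0, strand = "-",
        site_sequence = paste0(hit20, pam),
        n_mismatches = count_mismatches(hit20, protospacer),
        cut_site = st0 + 3L, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = integer(),
                      strand = character(), site_sequence = character(),
                      n_mismatches = integer(), cut_site = integer(),
                      stringsAsFactors = FALSE)
  }
  if (!is.null(locus) && nrow(out) > 0L) {
    on_t <- out$chrom == locus$chrom & out$cut_site == locus$cut_site &
      out$strand == locus$strand
    out <- out[!on_t, , drop = FALSE]
  }
  out$annotation <- rep("unannotated", nrow(out))
  if (!is.null(features) && nrow(out) > 0L && nrow(features) > 0L) {
    for (i in seq_len(nrow(out))) {
      hit <- features$chrom == out$chrom[i] &
        features$start < out$start[i] + 23L & features$end > out$start[i]
      if (any(hit)) out$annotation[i] <- features$name[which(hit)[1L]]
    }
  }
  out <- out[order(out$n_mismatches, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract the reference amplicon around an off-target cut site
#'
#' @param genome host genome
#' @param chrom,cut_site site location (0-based cut boundary)
#' @param flank_bp flank on each side
#' @return list with `reference` (DNA string) and `cut_site_in_amplicon`
#' @export
site_amplicon <- function(genome, chrom, cut_site, flank_bp = 150L) {
  genome <- as_genome(genome)
  seq <- genome[[chrom]]
  lo <- max(0L, cut_site - flank_bp)
  hi <- min(nchar(seq), cut_site + flank_bp)
  list(reference = substr(seq, lo + 1L, hi),
       cut_site_in_amplicon = cut_site - lo)
}

#' Per-site indel background screen
#'
#' Runs the cut-site-window indel caller at every site (including an
#' on-target row when present in `sites`) and flags sites whose indel
#' fraction exceeds `background_threshold`. Sites without reads are marked
#' `no-data` rather than raising an error.
#'
#' @param sites data.frame from [enumerate_offtargets()] (optionally with a
#'   `site_id` column; one is generated otherwise). The on-target site can
#'   be included as an extra row.
#' @param reads_per_site list of read vectors, one element per row of
#'   `sites`
#' @param genome host genome (source of the reference amplicons)
#' @param flank_bp amplicon flank around each cut site
#' @param window_bp,min_indel_len passed to [call_indels_window()]
#' @param background_threshold flagging threshold on the indel fraction
#'   (default 0.001, i.e. 0.1%)
#' @return data.frame: `site_id`, `chrom`, `cut_site`, `n_mismatches`,
#'   `n_reads`, `indel_fraction`, `flagged`, `status`
#' @export
screen_offtarget_indels <- function(sites, reads_per_site, genome,
                                    flank_bp = 150L, window_bp = 5L,
                                    min_indel_len = 1L,
                                    background_threshold = 0.001) {
  stopifnot(length(reads_per_site) == nrow(sites))
  ids <- if ("site_id" %in% names(sites)) sites$site_id else
    sprintf("OFT%02d", seq_len(nrow(sites)))
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    reads <- reads_per_site[[i]]
    base <- data.frame(site_id = ids[i], chrom = sites$chrom[i],
                       cut_site = sites$cut_site[i],
                       n_mismatches = sites$n_mismatches[i],
                       stringsAsFactors = FALSE)
    if (length(reads) == 0L) {
      base$n_reads <- 0L; base$indel_fraction <- NA_real_
      base$flagged <- NA; base$status <- "no-data"
      return(base)
    }
    amp <- site_amplicon(genome, sites$chrom[i], sites$cut_site[i], flank_bp)
    res <- call_indels_window(reads, amp$reference, amp$cut_site_in_amplicon,
                              window_bp = window_bp,
                              min_indel_len = min_indel_len)
    base$n_reads <- res$n_reads_analyzed
    base$indel_fraction <- res$indel_fraction
    base$flagged <- res$indel_fraction > background_threshold
    base$status <- "ok"
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare integration sites with predicted off-target sites
#'
#' For each integration site, reports the distance to the nearest predicted
#' off-target cut site on the same chromosome and whether the two
#' correspond at `distance_bp`.
#'
#' @param offtargets data.frame from [enumerate_offtargets()]
#' @param sites integration-site data.frame (from [cluster_sites()])
#' @param distance_bp correspondence threshold (bp)
#' @return data.frame: `host_chrom`, `representative_coord`,
#'   `nearest_offtarget_distance` (`NA` when no off-target on the
#'   chromosome), `correspond`
#' @export
compare_sites_to_integrations <- function(offtargets, sites,
                                          distance_bp = 1000L) {
  out <- data.frame(host_chrom = sites$host_chrom,
                    representative_coord = sites$representative_coord,
                    nearest_offtarget_distance = NA_real_,
                    correspond = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    same <- offtargets[offtargets$chrom == out$host_chrom[i], , drop = FALSE]
    if (nrow(same) == 0L) next
    d <- min(abs(same$cut_site - out$representative_coord[i]))
    out$nearest_offtarget_distance[i] <- d
    out$correspond[i] <- d <= distance_bp
  }
  out
}
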