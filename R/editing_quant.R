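## In-silico three-primer PCR and amplicon-based editing quantification.
##
## The assay uses two primers annealing to genomic sequence outside the
## homology arms plus a third primer inside the donor cDNA. Unedited and
## NHEJ alleles yield only the long outer-primer product (~2.5 kb in the
## assay this models); HDR knock-in alleles yield a shorter outer x cDNA
## product (~1.6 kb) while the outer-primer product exceeds the size cutoff.
## Episomal vector carries no outer-primer sites, so it never amplifies.

#' Construct a three-primer set
#'
#' @param p_out5 primer annealing to the host genome upstream of the 5' HA
#'   (forward)
#' @param p_out3 primer annealing downstream of the 3' HA, given 5'->3' on
#'   the minus strand (reverse)
#' @param p_cdna primer annealing within the donor cDNA, orientation opposing
#'   `p_out5` (reverse)
#' @return a `PrimerSet`
#' @export
primer_set <- function(p_out5, p_out3, p_cdna) {
  for (p in list(p_out5 = p_out5, p_out3 = p_out3, p_cdna = p_cdna)) {
    if (grepl("[^ACGT]", p)) {
      stop("invalid-primer: degenerate or non-ACGT bases not supported",
           call. = FALSE)
    }
    if (nchar(p) < 15L) stop("invalid-primer: primers must be >= 15 nt",
                             call. = FALSE)
  }
  structure(list(p_out5 = p_out5, p_out3 = p_out3, p_cdna = p_cdna),
            class = "PrimerSet")
}

## all binding sites of one primer on a template, both orientations.
## A forward site is a plus-strand match (primer extends rightward); a
## reverse site is a match of the reverse complement (primer extends
## leftward, its 5' end at the rightmost template base of the match).
## The 3'-terminal 3 nt must match exactly (PCR extension requirement).
primer_sites <- function(primer, template, max_mismatches) {
  subject <- Biostrings::DNAString(template)
  n <- nchar(primer)
  hits <- function(pat, orient) {
    mi <- Biostrings::matchPattern(Biostrings::DNAString(pat), subject,
                                   max.mismatch = max_mismatches,
                                   with.indels = FALSE)
    st <- BiocGenerics::start(mi) - 1L   # to 0-based
    en <- BiocGenerics::end(mi)
    keep <- vapply(seq_along(st), function(i) {
      hit <- substr(template, st[i] + 1L, en[i])
      if (orient == "fwd") {
        identical(substr(hit, n - 2L, n), substr(pat, n - 2L, n))
      } else {
        identical(substr(hit, 1L, 3L), substr(pat, 1L, 3L))
      }
    }, TRUE)
    data.frame(start = st[keep], end = en[keep],
               orient = rep(orient, sum(keep)), stringsAsFactors = FALSE)
  }
  rbind(hits(primer, "fwd"), hits(revcomp(primer), "rev"))
}

#' Predict PCR products of a primer set on a template
#'
#' Enumerates every orientation-compatible primer binding site with at most
#' `max_mismatches` mismatches (the 3'-terminal 3 nt must match exactly) and
#' reports every convergent forward/reverse pair whose product length falls
#' in `[min_len, max_len]`. Product length is the distance from the 5' end of
#' the forward site to the 5' end of the reverse site, inclusive.
#'
#' @param template template DNA string
#' @param primers a `PrimerSet` or named character vector of primers
#' @param max_mismatches mismatches tolerated per site (default 1)
#' @param min_len,max_len product length bounds (bp); the default
#'   `max_len = 3500` models the short-product amplification bias that
#'   suppresses very long outer-primer products
#' @return data.frame: `fwd_primer`, `rev_primer`, `start`, `end` (0-based
#'   half-open product interval), `length`
#' @export
insilico_pcr <- function(template, primers, max_mismatches = 1L,
                         min_len = 50L, max_len = 3500L) {
  if (inherits(primers, "PrimerSet")) primers <- unlist(unclass(primers))
  stopifnot(max_len > min_len, min_len >= 50L)
  for (p in primers) {
    if (grepl("[^ACGT]", p)) {
      stop("invalid-primer: degenerate or non-ACGT bases not supported",
           call. = FALSE)
    }
  }
  sites <- do.call(rbind, lapply(names(primers), function(nm) {
    s <- primer_sites(primers[[nm]], template, max_mismatches)
    if (nrow(s)) s$primer <- nm else s$primer <- character(0)
    s
  }))
  out <- data.frame(fwd_primer = character(), rev_primer = character(),
                    start = integer(), end = integer(), length = integer(),
                    stringsAsFactors = FALSE)
  if (is.null(sites) || nrow(sites) == 0L) return(out)
  fwd <- sites[sites$orient == "fwd", , drop = FALSE]
  rev <- sites[sites$orient == "rev", , drop = FALSE]
  for (i in seq_len(nrow(fwd))) {
    for (j in seq_len(nrow(rev))) {
      len <- rev$end[j] - fwd$start[i]   # rev 5' - fwd 5' + 1
      if (rev$start[j] <= fwd$start[i]) next          # not convergent
      if (len < min_len || len > max_len) next
      out <- rbind(out, data.frame(
        fwd_primer = fwd$primer[i], rev_primer = rev$primer[j],
        start = fwd$start[i], end = rev$end[j], length = len,
        stringsAsFactors = FALSE))
    }
  }
  out[order(out$start, out$length), , drop = FALSE]
}

#' Predict the three-primer band pattern for a set of alleles
#'
#' Runs [insilico_pcr()] on each allele and maps products to band classes:
#' the outer-primer product (`p_out5` x `p_out3`) is the `WT/NHEJ` band, any
#' product involving `p_cdna` is an `HDR` band.
#'
#' @param alleles named list of `AlleleModel`s or DNA strings (names used as
#'   allele labels)
#' @param primers a `PrimerSet`
#' @inheritParams insilico_pcr
#' @return data.frame: `allele`, `allele_class`, `length`, `start`, `end`
#' @export
predict_bands <- function(alleles, primers, max_mismatches = 1L,
                          min_len = 50L, max_len = 3500L) {
  rows <- lapply(names(alleles), function(nm) {
    a <- alleles[[nm]]
    seq <- if (inherits(a, "AlleleModel")) a$sequence else a
    pr <- insilico_pcr(seq, primers, max_mismatches, min_len, max_len)
    if (nrow(pr) == 0L) return(NULL)
    pr$allele <- nm
    pr$allele_class <- ifelse(pr$fwd_primer == "p_cdna" |
                                pr$rev_primer == "p_cdna", "HDR", "WT/NHEJ")
    pr[, c("allele", "allele_class", "length", "start", "end")]
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(allele = character(), allele_class = character(),
                      length = integer(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' HDR fraction from band intensities
#'
#' `hdr_fraction = intensity(HDR) / sum(intensities)`, as when quantifying
#' relative band intensities on a gel. With `molar_correction = TRUE` each
#' intensity is first divided by its product length (mass -> molar), off by
#' default.
#'
#' @param bands data.frame with `allele_class` (`"WT/NHEJ"` or `"HDR"`),
#'   `predicted_length`, `intensity`
#' @param molar_correction divide intensities by length before the ratio
#' @return HDR fraction in `[0, 1]`
#' @examples
#' bands <- data.frame(allele_class = c("HDR", "WT/NHEJ"),
#'                     predicted_length = c(1600, 2500),
#'                     intensity = c(200, 800))
#' quantify_hdr_from_bands(bands)  # 0.2
#' @export
quantify_hdr_from_bands <- function(bands, molar_correction = FALSE) {
  stopifnot(all(bands$intensity >= 0))
  w <- bands$intensity
  if (molar_correction) w <- w / bands$predicted_length
  tot <- sum(w)
  if (tot == 0) stop("undefined-ratio: all band intensities are zero",
                     call. = FALSE)
  sum(w[bands$allele_class == "HDR"]) / tot
}

#' Band table from classified amplicon reads
#'
#' Each read is assigned to the predicted band whose length is nearest its
#' own (within `max_rel_diff`); intensity is the read count per band class.
#'
#' @param read_lengths integer vector of read lengths
#' @param band_defs data.frame with `allele_class` and `length` (one row per
#'   band class; duplicates collapsed to the first length per class)
#' @param max_rel_diff maximum relative length difference for assignment
#' @return data.frame `allele_class`, `predicted_length`, `intensity`,
#'   `fraction` (of assigned reads)
#' @export
band_table_from_reads <- function(read_lengths, band_defs,
                                  max_rel_diff = 0.2) {
  defs <- band_defs[!duplicated(band_defs$allele_class), , drop = FALSE]
  assign_one <- function(len) {
    d <- abs(defs$length - len) / defs$length
    i <- which.min(d)
    if (length(i) == 0L || d[i] > max_rel_diff) NA_character_
    else defs$allele_class[i]
  }
  cls <- vapply(read_lengths, assign_one, "")
  counts <- vapply(defs$allele_class, function(k) sum(cls == k, na.rm = TRUE),
                   0L)
  out <- data.frame(allele_class = defs$allele_class,
                    predicted_length = defs$length,
                    intensity = as.numeric(counts),
                    stringsAsFactors = FALSE)
  out$fraction <- if (sum(counts) > 0) out$intensity / sum(counts) else 0
  rownames(out) <- NULL
  out
}

#' Banded global alignment of an amplicon read to its reference
#'
#' Affine-gap Needleman-Wunsch restricted to a diagonal band. A gap of
#' length k scores `gap_open + k * gap_extend`. Ties are broken
#' deterministically: match/mismatch over a gap, then gap-in-read (CIGAR D)
#' over gap-in-reference (CIGAR I). Whenever the true indel size is smaller
#' than `band_width` the banded score equals the unbanded optimum.
#'
#' @param read,reference_amplicon DNA strings
#' @param band_width half-width of the diagonal band; must be at least the
#'   length difference of the two sequences
#' @param match,mismatch,gap_open,gap_extend scoring scheme
#' @return list with `score` and `cigar` (M/I/D; read is the query: I
#'   consumes read, D consumes reference)
#' @export
align_amplicon <- function(read, reference_amplicon, band_width = 50L,
                           match = 2, mismatch = -4, gap_open = -6,
                           gap_extend = -1) {
  if (abs(nchar(read) - nchar(reference_amplicon)) > band_width) {
    stop("band-width error: length difference exceeds band_width",
         call. = FALSE)
  }
  banded_align_cpp(read, reference_amplicon, as.integer(band_width),
                   match, mismatch, gap_open, gap_extend)
}

## walk an M/I/D cigar against a reference offset; returns a data.frame of
## indel events (type, ref_pos, len) and the mismatch count vs the reference
alignment_events <- function(read, reference, cigar) {
  ops <- parse_cigar(cigar)
  rpos <- 0L; qpos <- 0L
  ev <- list(); mism <- 0L
  for (i in seq_len(nrow(ops))) {
    len <- ops$len[i]; op <- ops$op[i]
    if (op == "M") {
      a <- substr(read, qpos + 1L, qpos + len)
      b <- substr(reference, rpos + 1L, rpos + len)
      if (!identical(a, b)) {
        mism <- mism + sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
      }
      rpos <- rpos + len; qpos <- qpos + len
    } else if (op == "I") {
      ev[[length(ev) + 1L]] <- data.frame(type = "I", ref_pos = rpos,
                                          len = len)
      qpos <- qpos + len
    } else if (op == "D") {
      ev[[length(ev) + 1L]] <- data.frame(type = "D", ref_pos = rpos,
                                          len = len)
      rpos <- rpos + len
    } else stop("unexpected CIGAR op ", op, call. = FALSE)
  }
  list(indels = if (length(ev)) do.call(rbind, ev) else
         data.frame(type = character(), ref_pos = integer(), len = integer()),
       mismatches = mism)
}

indel_overlaps_window <- function(indels, lo, hi, min_indel_len) {
  if (nrow(indels) == 0L) return(FALSE)
  keep <- indels$len >= min_indel_len
  ins <- keep & indels$type == "I" &
    indels$ref_pos >= lo & indels$ref_pos <= hi
  del <- keep & indels$type == "D" &
    indels$ref_pos < hi & (indels$ref_pos + indels$len) > lo
  any(ins | del)
}

#' Call indels in a window around the cut site from amplicon reads
#'
#' Each read is aligned to the reference amplicon with [align_amplicon()]; a
#' read is indel-positive when its alignment contains an insertion or
#' deletion of at least `min_indel_len` bases overlapping
#' `[cut_site - window_bp, cut_site + window_bp)`. Reads that cannot be
#' aligned (length difference beyond the band, or alignment identity below
#' `min_identity`) are excluded from the denominator and counted separately.
#'
#' @param reads character vector of read sequences (names used as ids)
#' @param reference_amplicon reference amplicon sequence
#' @param cut_site_in_amplicon 0-based cut position within the amplicon
#' @param window_bp half-width of the window (default 5)
#' @param min_indel_len minimum indel length counted (default 1)
#' @param band_width,min_identity alignment guards
#' @inheritParams align_amplicon
#' @return list: `indel_fraction`, `n_reads_analyzed`, `n_failed`,
#'   `per_read` data.frame (`read_id`, `analyzed`, `indel`)
#' @export
call_indels_window <- function(reads, reference_amplicon,
                               cut_site_in_amplicon, window_bp = 5L,
                               min_indel_len = 1L, band_width = 50L,
                               min_identity = 0.7, match = 2, mismatch = -4,
                               gap_open = -6, gap_extend = -1) {
  stopifnot(window_bp >= 1L)
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(reads))
  lo <- cut_site_in_amplicon - window_bp
  hi <- cut_site_in_amplicon + window_bp
  analyzed <- logical(length(reads)); positive <- logical(length(reads))
  for (i in seq_along(reads)) {
    r <- reads[[i]]
    if (abs(nchar(r) - nchar(reference_amplicon)) > band_width) next
    al <- align_amplicon(r, reference_amplicon, band_width, match, mismatch,
                         gap_open, gap_extend)
    ev <- alignment_events(r, reference_amplicon, al$cigar)
    ident <- 1 - (ev$mismatches + sum(ev$indels$len)) /
      max(nchar(r), nchar(reference_amplicon))
    if (ident < min_identity) next
    analyzed[i] <- TRUE
    positive[i] <- indel_overlaps_window(ev$indels, lo, hi, min_indel_len)
  }
  if (!any(analyzed)) stop("no-data: zero analyzable reads", call. = FALSE)
  list(indel_fraction = sum(positive) / sum(analyzed),
       n_reads_analyzed = sum(analyzed),
       n_failed = sum(!analyzed),
       per_read = data.frame(read_id = ids, analyzed = analyzed,
                             indel = positive, stringsAsFactors = FALSE))
}

#' Verify homology-arm junction fidelity of the HDR allele
#'
#' Aligns reads spanning one HA junction of the knock-in allele to the
#' expected junction region (`+/- flank_bp` around the insert boundary) and
#' builds a consensus. The verdict is `"precise"` when the consensus carries
#' no indel and at most `max_allowed_mismatches` mismatches in the region.
#'
#' @param reads character vector of reads spanning the junction
#' @param hdr_allele `AlleleModel` from [build_hdr_allele()]
#' @param junction `"5prime"` or `"3prime"`
#' @param flank_bp flank on each side of the junction (>= 20)
#' @param max_allowed_mismatches consensus mismatch tolerance (default 0)
#' @param band_width,min_identity alignment guards as in
#'   [call_indels_window()]
#' @return list: `verdict` (`"precise"`, `"imprecise"`, or `"no-data"`),
#'   `consensus_mismatches`, `consensus_indels`, `n_reads_analyzed`,
#'   `n_failed`, `per_read` data.frame (`mismatches`, `indels`)
#' @export
verify_junction_fidelity <- function(reads, hdr_allele,
                                     junction = c("5prime", "3prime"),
                                     flank_bp = 100L,
                                     max_allowed_mismatches = 0L,
                                     band_width = 50L, min_identity = 0.7) {
  junction <- match.arg(junction)
  stopifnot(flank_bp >= 20L)
  iv <- attr(hdr_allele, "insert_interval")
  if (is.null(iv) || hdr_allele$label != "HDR") {
    stop("model error: allele lacks an insert junction", call. = FALSE)
  }
  pos <- if (junction == "5prime") iv[1] else iv[2]
  if (pos - flank_bp < 0L || pos + flank_bp > nchar(hdr_allele$sequence)) {
    stop("model error: junction region extends beyond the allele",
         call. = FALSE)
  }
  region <- substr(hdr_allele$sequence, pos - flank_bp + 1L, pos + flank_bp)
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(reads))
  n_ref <- nchar(region)
  base_counts <- matrix(0L, nrow = 5L, ncol = n_ref,
                        dimnames = list(c("A", "C", "G", "T", "-"), NULL))
  indel_keys <- character()
  per_mm <- integer(0); per_ind <- integer(0); per_id <- character(0)
  n_failed <- 0L
  for (i in seq_along(reads)) {
    r <- reads[[i]]
    if (abs(nchar(r) - n_ref) > band_width) { n_failed <- n_failed + 1L; next }
    al <- align_amplicon(r, region, band_width)
    ev <- alignment_events(r, region, al$cigar)
    ident <- 1 - (ev$mismatches + sum(ev$indels$len)) / max(nchar(r), n_ref)
    if (ident < min_identity) { n_failed <- n_failed + 1L; next }
    ## tally per-position bases
    ops <- parse_cigar(al$cigar)
    rpos <- 0L; qpos <- 0L
    for (k in seq_len(nrow(ops))) {
      len <- ops$len[k]; op <- ops$op[k]
      if (op == "M") {
        bases <- strsplit(substr(r, qpos + 1L, qpos + len), "")[[1]]
        for (b in seq_len(len)) {
          base_counts[bases[b], rpos + b] <- base_counts[bases[b], rpos + b] + 1L
        }
        rpos <- rpos + len; qpos <- qpos + len
      } else if (op == "D") {
        base_counts["-", (rpos + 1L):(rpos + len)] <-
          base_counts["-", (rpos + 1L):(rpos + len)] + 1L
        rpos <- rpos + len
      } else {
        qpos <- qpos + len
      }
    }
    if (nrow(ev$indels)) {
      indel_keys <- c(indel_keys, paste(ev$indels$type, ev$indels$ref_pos,
                                        ev$indels$len, sep = ":"))
    }
    per_id <- c(per_id, ids[i])
    per_mm <- c(per_mm, ev$mismatches)
    per_ind <- c(per_ind, nrow(ev$indels))
  }
  n_ok <- length(per_id)
  if (n_ok == 0L) {
    return(list(verdict = "no-data", consensus_mismatches = NA_integer_,
                consensus_indels = NA_integer_, n_reads_analyzed = 0L,
                n_failed = n_failed,
                per_read = data.frame(read_id = character(),
                                      mismatches = integer(),
                                      indels = integer())))
  }
  covered <- colSums(base_counts) > 0L
  cons <- rep(NA_character_, n_ref)
  cons[covered] <- rownames(base_counts)[
    apply(base_counts[, covered, drop = FALSE], 2L, which.max)]
  ref_bases <- strsplit(region, "")[[1]]
  consensus_mismatches <- sum(covered & cons != ref_bases & cons != "-",
                              na.rm = TRUE)
  tab <- table(indel_keys)
  consensus_indels <- sum(tab > n_ok / 2) +
    sum(covered & cons == "-", na.rm = TRUE)
  verdict <- if (consensus_indels == 0L &&
                 consensus_mismatches <= max_allowed_mismatches) {
    "precise"
  } else "imprecise"
  list(verdict = verdict, consensus_mismatches = consensus_mismatches,
       consensus_indels = consensus_indels, n_reads_analyzed = n_ok,
       n_failed = n_failed,
       per_read = data.frame(read_id = per_id, mismatches = per_mm,
                             indels = per_ind, stringsAsFactors = FALSE))
}
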