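## Vector-host junction detection from chimeric long-read alignments.
##
## A read spanning an integration junction aligns in pieces: one piece to the
## vector contig of the combined reference and one to a host chromosome, the
## aligner recording the partner piece in the SA:Z tag. Junctions are found by
## taking each primary record plus its SA entries, turning every CIGAR into a
## (read interval, reference interval) pair, and looking for adjacent
## vector/host pieces along the read.

CIGAR_RE <- "^([0-9]+[MIDNSHP=X])+$"

parse_cigar <- function(cigar) {
  if (is.na(cigar) || !grepl(CIGAR_RE, cigar)) {
    stop("malformed CIGAR: '", cigar, "'", call. = FALSE)
  }
  m <- gregexpr("[0-9]+|[MIDNSHP=X]", cigar)[[1]]
  tok <- regmatches(cigar, list(m))[[1]]
  data.frame(len = as.integer(tok[c(TRUE, FALSE)]),
             op = tok[c(FALSE, TRUE)], stringsAsFactors = FALSE)
}

cigar_query_length <- function(cigar) {
  ops <- parse_cigar(cigar)
  sum(ops$len[ops$op %in% c("M", "I", "S", "H", "=", "X")])
}

#' Parse a SAM SA:Z supplementary-alignment tag
#'
#' The tag value is a semicolon-terminated list of
#' `rname,pos,strand,CIGAR,mapQ,NM;` entries with 1-based `pos`. Positions
#' are converted to the package's 0-based convention; strand and CIGAR are
#' preserved verbatim.
#'
#' @param tag_value the string after `SA:Z:` (may be `""`)
#' @return data.frame with one row per entry: `reference`, `ref_start`
#'   (0-based), `strand`, `cigar`, `mapq`
#' @examples
#' parse_sa_tag("chr3,1000,+,500S4500M,60,12;")
#' @export
parse_sa_tag <- function(tag_value) {
  empty <- data.frame(reference = character(), ref_start = integer(),
                      strand = character(), cigar = character(),
                      mapq = integer(), stringsAsFactors = FALSE)
  if (is.na(tag_value) || !nzchar(tag_value)) return(empty)
  entries <- strsplit(tag_value, ";", fixed = TRUE)[[1]]
  entries <- entries[nzchar(entries)]
  if (length(entries) == 0L) return(empty)
  rows <- lapply(entries, function(e) {
    f <- strsplit(e, ",", fixed = TRUE)[[1]]
    bad <- function(why) stop("malformed SA entry '", e, "': ", why,
                              call. = FALSE)
    if (length(f) != 6L) bad("expected 6 comma-separated fields")
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos) || pos < 1L) bad("pos must be an integer >= 1")
    if (!f[3] %in% c("+", "-")) bad("strand must be + or -")
    if (!grepl(CIGAR_RE, f[4])) bad("invalid CIGAR")
    mapq <- suppressWarnings(as.integer(f[5]))
    if (is.na(mapq)) bad("invalid mapQ")
    data.frame(reference = f[1], ref_start = pos - 1L, strand = f[3],
               cigar = f[4], mapq = mapq, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read and reference intervals implied by a CIGAR string
#'
#' Soft/hard clips delimit the aligned portion of the read; for a
#' minus-strand alignment the clip arithmetic is flipped so that the returned
#' read interval is in the original read orientation. All intervals are
#' 0-based half-open.
#'
#' @param cigar CIGAR string (operators M, I, D, N, S, H, =, X)
#' @param ref_start 0-based leftmost reference position of the alignment
#' @param strand `"+"` or `"-"`
#' @param read_length full read length; must equal the CIGAR query length
#' @return list with `read_interval` and `ref_interval`, each `c(start, end)`
#' @export
cigar_intervals <- function(cigar, ref_start, strand, read_length) {
  ops <- parse_cigar(cigar)
  qlen <- sum(ops$len[ops$op %in% c("M", "I", "S", "H", "=", "X")])
  if (qlen != read_length) {
    stop("CIGAR query length (", qlen, ") inconsistent with read_length (",
         read_length, ")", call. = FALSE)
  }
  clip_ops <- ops$op %in% c("S", "H")
  lead <- 0L
  for (i in seq_len(nrow(ops))) {
    if (!clip_ops[i]) break
    lead <- lead + ops$len[i]
  }
  trail <- 0L
  for (i in rev(seq_len(nrow(ops)))) {
    if (!clip_ops[i]) break
    trail <- trail + ops$len[i]
  }
  if (strand == "+") {
    read_iv <- c(lead, read_length - trail)
  } else {
    read_iv <- c(trail, read_length - lead)
  }
  ref_len <- sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])
  list(read_interval = as.integer(read_iv),
       ref_interval = as.integer(c(ref_start, ref_start + ref_len)))
}

#' Decompose a primary alignment plus its SA tag into chimeric segments
#'
#' @param record a list/one-row data.frame with `reference`, `ref_start`
#'   (0-based), `strand`, `cigar`, `mapq` and optionally `sa` (the SA:Z value)
#' @param read_length full read length
#' @param max_overlap reads whose segments overlap on the read by more than
#'   this many bases (microhomology tolerance) are ambiguous: a warning is
#'   raised and `NULL` returned
#' @return data.frame of segments sorted by read start (`reference`,
#'   `ref_start`, `ref_end`, `read_start`, `read_end`, `strand`, `cigar`,
#'   `mapq`, `is_supplementary`), or `NULL` for ambiguous chimeras
#' @export
extract_chimeric_segments <- function(record, read_length, max_overlap = 50L) {
  stubs <- data.frame(reference = record$reference,
                      ref_start = record$ref_start, strand = record$strand,
                      cigar = record$cigar, mapq = record$mapq,
                      stringsAsFactors = FALSE)
  sa <- if (!is.null(record$sa)) record$sa else NA_character_
  stubs <- rbind(stubs, parse_sa_tag(if (is.na(sa)) "" else sa))
  stubs$is_supplementary <- c(FALSE, rep(TRUE, nrow(stubs) - 1L))
  ivs <- lapply(seq_len(nrow(stubs)), function(i) {
    cigar_intervals(stubs$cigar[i], stubs$ref_start[i], stubs$strand[i],
                    read_length)
  })
  segs <- data.frame(
    reference = stubs$reference,
    ref_start = vapply(ivs, function(x) x$ref_interval[1], 0L),
    ref_end = vapply(ivs, function(x) x$ref_interval[2], 0L),
    read_start = vapply(ivs, function(x) x$read_interval[1], 0L),
    read_end = vapply(ivs, function(x) x$read_interval[2], 0L),
    strand = stubs$strand, cigar = stubs$cigar, mapq = stubs$mapq,
    is_supplementary = stubs$is_supplementary, stringsAsFactors = FALSE)
  segs <- segs[order(segs$read_start, segs$read_end), , drop = FALSE]
  rownames(segs) <- NULL
  if (nrow(segs) > 1L) {
    overlap <- segs$read_end[-nrow(segs)] - segs$read_start[-1L]
    if (any(overlap > max_overlap)) {
      warning("ambiguous chimera: segments overlap by ", max(overlap),
              " bp on the read (> ", max_overlap, "); read skipped")
      return(NULL)
    }
  }
  segs
}

#' Call vector-host junction events from one read's chimeric segments
#'
#' Every adjacent pair of segments along the read in which exactly one
#' segment lies on the vector contig, both pass the mapq and length filters,
#' and the unaligned gap between them on the read is small, yields one
#' junction event. The reported coordinate on each reference is the boundary
#' coordinate facing the junction: the segment's reference end if the
#' junction sits at its right read-edge on the plus strand (mirrored for
#' minus-strand segments), otherwise its reference start.
#'
#' @param segments data.frame from [extract_chimeric_segments()]
#' @param vector_contig_name name of the vector contig
#' @param vector_map a `VectorMap`, used to label which vector segment (ITR,
#'   HA, cDNA, ...) the junction falls in
#' @param min_mapq,min_segment_len,max_junction_gap filters; defaults suit
#'   ~2% error long reads
#' @param read_id read name copied into the events
#' @return data.frame of `JunctionEvent`s: `read_id`, `vector_coord`,
#'   `vector_segment`, `host_chrom`, `host_coord`, `orientation`, `read_gap`
#' @export
call_junctions <- function(segments, vector_contig_name, vector_map,
                           min_mapq = 20L, min_segment_len = 200L,
                           max_junction_gap = 100L, read_id = NA_character_) {
  empty <- data.frame(read_id = character(), vector_coord = integer(),
                      vector_segment = character(), host_chrom = character(),
                      host_coord = integer(), orientation = character(),
                      read_gap = integer(), stringsAsFactors = FALSE)
  if (is.null(segments) || nrow(segments) < 2L) return(empty)
  ## coordinate facing the junction for the left (A) and right (B) member
  facing <- function(seg, side) {
    right_ref_edge <- (side == "left") == (seg$strand == "+")
    if (right_ref_edge) c(coord = seg$ref_end, adjacent = seg$ref_end - 1L)
    else c(coord = seg$ref_start, adjacent = seg$ref_start)
  }
  out <- list()
  for (i in seq_len(nrow(segments) - 1L)) {
    a <- segments[i, ]; b <- segments[i + 1L, ]
    a_vec <- a$reference == vector_contig_name
    b_vec <- b$reference == vector_contig_name
    if (a_vec == b_vec) next
    len_a <- a$read_end - a$read_start; len_b <- b$read_end - b$read_start
    if (min(a$mapq, b$mapq) < min_mapq) next
    if (min(len_a, len_b) < min_segment_len) next
    gap <- b$read_start - a$read_end
    if (abs(gap) > max_junction_gap) next
    fa <- facing(a, "left"); fb <- facing(b, "right")
    vec <- if (a_vec) fa else fb
    host <- if (a_vec) fb else fa
    host_seg <- if (a_vec) b else a
    out[[length(out) + 1L]] <- data.frame(
      read_id = read_id, vector_coord = unname(vec["coord"]),
      vector_segment = vector_segment_at(vector_map, unname(vec["adjacent"])),
      host_chrom = host_seg$reference, host_coord = unname(host["coord"]),
      orientation = if (a_vec) "vector->host" else "host->vector",
      read_gap = gap, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

#' Cluster junction events into integration sites
#'
#' Single-linkage clustering of host coordinates per chromosome: events whose
#' coordinates are within `merge_distance` of another member join the same
#' site. The representative coordinate is the lower median of member
#' coordinates; support counts distinct reads.
#'
#' @param events data.frame of junction events (from [call_junctions()],
#'   possibly concatenated over reads)
#' @param merge_distance maximum coordinate gap joining two events (bp)
#' @return data.frame of `IntegrationSite`s ordered by (chrom,
#'   representative_coord): `host_chrom`, `representative_coord`, `support`,
#'   `n_events`, `classification` (`NA` until [classify_sites()]), plus a
#'   `members` list-column of member event data.frames
#' @export
cluster_sites <- function(events, merge_distance = 50L) {
  empty <- data.frame(host_chrom = character(), representative_coord = integer(),
                      support = integer(), n_events = integer(),
                      classification = character(), stringsAsFactors = FALSE)
  empty$members <- list()
  if (is.null(events) || nrow(events) == 0L) return(empty)
  stopifnot(merge_distance >= 0)
  out <- list()
  for (chrom in sort(unique(events$host_chrom))) {
    ev <- events[events$host_chrom == chrom, , drop = FALSE]
    ev <- ev[order(ev$host_coord), , drop = FALSE]
    gaps <- diff(ev$host_coord)
    cluster_id <- cumsum(c(1L, as.integer(gaps > merge_distance)))
    for (cl in unique(cluster_id)) {
      mem <- ev[cluster_id == cl, , drop = FALSE]
      row <- data.frame(host_chrom = chrom,
                        representative_coord = lower_median(mem$host_coord),
                        support = length(unique(mem$read_id)),
                        n_events = nrow(mem),
                        classification = NA_character_,
                        stringsAsFactors = FALSE)
      row$members <- list(mem)
      out[[length(out) + 1L]] <- row
    }
  }
  sites <- do.call(rbind, out)
  sites <- sites[order(sites$host_chrom, sites$representative_coord), ,
                 drop = FALSE]
  rownames(sites) <- NULL
  sites
}

#' Classify integration sites as targeted or other
#'
#' A site is `targeted` when it lies on the locus chromosome within
#' `targeted_window` bp of the homology-arm span (from the start of the 5' HA
#' to the end of the 3' HA); everything else is `other`. For each site the
#' distance to the nearest predicted off-target site (same chromosome) is
#' reported, `NA` when none exists.
#'
#' @param sites data.frame from [cluster_sites()]
#' @param locus a `TargetLocus`
#' @param targeted_window slack around the homology-arm span (bp)
#' @param predicted_offtargets optional data.frame with `chrom` and `cut_site`
#'   columns (e.g. from [enumerate_offtargets()])
#' @return `sites` with `classification` filled in and a
#'   `nearest_offtarget_distance` column added
#' @export
classify_sites <- function(sites, locus, targeted_window = 1000L,
                           predicted_offtargets = NULL) {
  stopifnot(targeted_window >= 0)
  if (nrow(sites) == 0L) {
    sites$nearest_offtarget_distance <- numeric(0)
    return(sites)
  }
  span <- c(locus$ha5_interval[1] - targeted_window,
            locus$ha3_interval[2] + targeted_window)
  sites$classification <- ifelse(
    sites$host_chrom == locus$chrom &
      sites$representative_coord >= span[1] &
      sites$representative_coord <= span[2],
    "targeted", "other")
  sites$nearest_offtarget_distance <- vapply(seq_len(nrow(sites)), function(i) {
    if (is.null(predicted_offtargets) || nrow(predicted_offtargets) == 0L) {
      return(NA_real_)
    }
    same <- predicted_offtargets[
      predicted_offtargets$chrom == sites$host_chrom[i], , drop = FALSE]
    if (nrow(same) == 0L) return(NA_real_)
    min(abs(same$cut_site - sites$representative_coord[i]))
  }, 0)
  sites
}

#' Read primary alignment records from a SAM file
#'
#' Keeps mapped primary records (secondary and supplementary lines are
#' represented through the primaries' SA tags). Positions are converted to
#' 0-based; the full read length is recovered from the CIGAR query length so
#' records without stored sequence (`SEQ = *`) also work.
#'
#' @param path SAM file path
#' @return data.frame with `qname`, `reference`, `ref_start`, `strand`,
#'   `cigar`, `mapq`, `sa`, `read_length`
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  empty <- data.frame(qname = character(), reference = character(),
                      ref_start = integer(), strand = character(),
                      cigar = character(), mapq = integer(), sa = character(),
                      read_length = integer(), stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  rows <- lapply(fields, function(f) {
    if (length(f) < 11L) stop("malformed SAM record: fewer than 11 fields",
                              call. = FALSE)
    flag <- suppressWarnings(as.integer(f[2]))
    if (is.na(flag)) stop("malformed SAM record: bad FLAG", call. = FALSE)
    if (bitwAnd(flag, 0x4L) != 0L) return(NULL)        # unmapped
    if (bitwAnd(flag, 0x100L) != 0L) return(NULL)      # secondary
    if (bitwAnd(flag, 0x800L) != 0L) return(NULL)      # supplementary
    opt <- f[-(1:11)]
    sa <- opt[startsWith(opt, "SA:Z:")]
    data.frame(qname = f[1], reference = f[3],
               ref_start = as.integer(f[4]) - 1L,
               strand = if (bitwAnd(flag, 0x10L) != 0L) "-" else "+",
               cigar = f[6], mapq = as.integer(f[5]),
               sa = if (length(sa)) sub("^SA:Z:", "", sa[1]) else NA_character_,
               read_length = cigar_query_length(f[6]),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Call junction events for every read in a SAM record table
#'
#' Convenience wrapper: runs [extract_chimeric_segments()] and
#' [call_junctions()] over each primary record.
#'
#' @param records data.frame from [read_sam()]
#' @inheritParams call_junctions
#' @param max_overlap passed to [extract_chimeric_segments()]
#' @return concatenated junction-event data.frame
#' @export
junctions_from_sam <- function(records, vector_contig_name, vector_map,
                               min_mapq = 20L, min_segment_len = 200L,
                               max_junction_gap = 100L, max_overlap = 50L) {
  out <- lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, ]
    segs <- extract_chimeric_segments(rec, rec$read_length,
                                      max_overlap = max_overlap)
    call_junctions(segs, vector_contig_name, vector_map, min_mapq,
                   min_segment_len, max_junction_gap, read_id = rec$qname)
  })
  ev <- do.call(rbind, out)
  if (is.null(ev)) {
    ev <- call_junctions(NULL, vector_contig_name, vector_map)
  }
  rownames(ev) <- NULL
  ev
}

#' Write integration sites as BED6
#'
#' Name column carries the classification, score the read support; intervals
#' are width-1, 0-based half-open.
#'
#' @param sites classified site data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_sites_bed <- function(sites, path) {
  bed <- data.frame(chrom = sites$host_chrom,
                    start = sites$representative_coord,
                    end = sites$representative_coord + 1L,
                    name = ifelse(is.na(sites$classification), ".",
                                  sites$classification),
                    score = sites$support, strand = ".")
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
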