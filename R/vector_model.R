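## Vector map, combined reference and allele models for the targeted locus.
##
## The donor is an AAV vector laid out ITR - 5'HA - cDNA - polyA - 3'HA - ITR:
## a promoterless cDNA with a polyA signal, flanked by 1-kb homology arms and
## the serotype ITRs. The combined reference used for long-read alignment is
## the host genome with the vector appended as one extra contig.

SEGMENT_LABELS <- c("ITR5", "HA5", "CDNA", "POLYA", "HA3", "ITR3")

#' Build an annotated AAV vector map
#'
#' Concatenates ITR + 5'HA + cDNA + polyA + 3'HA + ITR and records the
#' 0-based half-open coordinates of each segment.
#'
#' @param ha5,cdna,polya,ha3,itr DNA strings (A/C/G/T only). `itr` is used for
#'   both terminal repeats (the 3' ITR is stored as given; orientation is not
#'   modelled).
#' @param name contig name for the vector (default `"pAAV"`)
#' @return a `VectorMap`: list with `name`, `sequence`, and a `segments`
#'   data.frame (`label`, `start`, `end`)
#' @examples
#' vm <- build_vector_map(ha5 = strrep("A", 5), cdna = strrep("C", 5),
#'                        polya = strrep("G", 5), ha3 = strrep("T", 5),
#'                        itr = "ACGTA")
#' vm$segments
#' @export
build_vector_map <- function(ha5, cdna, polya, ha3, itr, name = "pAAV") {
  assert_dna(itr); assert_dna(ha5); assert_dna(cdna)
  assert_dna(polya); assert_dna(ha3)
  parts <- c(ITR5 = itr, HA5 = ha5, CDNA = cdna, POLYA = polya,
             HA3 = ha3, ITR3 = itr)
  lens <- nchar(parts)
  ends <- cumsum(lens)
  starts <- ends - lens
  vm <- structure(list(
    name = name,
    sequence = paste(parts, collapse = ""),
    segments = data.frame(label = SEGMENT_LABELS, start = unname(starts),
                          end = unname(ends), stringsAsFactors = FALSE)
  ), class = "VectorMap")
  vm
}

#' @export
print.VectorMap <- function(x, ...) {
  cat(sprintf("VectorMap '%s' (%d bp)\n", x$name, nchar(x$sequence)))
  print(x$segments, row.names = FALSE)
  invisible(x)
}

vector_segment_seq <- function(vm, label) {
  row <- vm$segments[vm$segments$label == label, ]
  substr(vm$sequence, row$start + 1L, row$end)
}

## which segment contains 0-based position `pos` (NA if in a gap / outside)
vector_segment_at <- function(vm, pos) {
  hit <- vm$segments$start <= pos & pos < vm$segments$end
  if (!any(hit)) NA_character_ else vm$segments$label[which(hit)[1L]]
}

#' Serialize a vector map as BED plus a JSON sidecar
#'
#' @param vm a `VectorMap`
#' @param bed_path,json_path output paths (BED is 0-based half-open)
#' @return invisibly, a list of the two paths
#' @export
write_vector_map <- function(vm, bed_path, json_path) {
  bed <- data.frame(chrom = vm$name, start = vm$segments$start,
                    end = vm$segments$end, name = vm$segments$label)
  write.table(bed, bed_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(name = vm$name, length = nchar(vm$sequence),
                            sequence = vm$sequence,
                            segments = vm$segments),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(list(bed = bed_path, json = json_path))
}

#' Read a vector map from its JSON sidecar
#' @param json_path path written by [write_vector_map()]
#' @return a `VectorMap`
#' @export
read_vector_map <- function(json_path) {
  x <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  structure(list(name = x$name, sequence = x$sequence,
                 segments = as.data.frame(x$segments)),
            class = "VectorMap")
}

#' Describe the targeted host locus
#'
#' Records where the guide cuts and which host intervals the donor homology
#' arms mirror. The cut site is the blunt SpCas9 cut 3 bp 5' of the PAM,
#' i.e. between protospacer bases 17 and 18; `cut_site` is the 0-based
#' boundary between the two flanking bases.
#'
#' @param chrom host contig name
#' @param strand `"+"` or `"-"` (strand carrying the protospacer)
#' @param cut_site 0-based position of the cut boundary on `chrom`
#' @param protospacer 20-nt guide sequence (5'->3' on `strand`)
#' @param pam 3-nt PAM (NGG for SpCas9)
#' @param ha5_interval,ha3_interval length-2 integer vectors, 0-based
#'   half-open host intervals homologous to the vector homology arms;
#'   `ha5_interval` must end at or before `cut_site`, `ha3_interval` must
#'   start at or after it
#' @return a `TargetLocus`
#' @export
target_locus <- function(chrom, strand, cut_site, protospacer, pam,
                         ha5_interval, ha3_interval) {
  stopifnot(strand %in% c("+", "-"), interval_ok(ha5_interval),
            interval_ok(ha3_interval))
  assert_dna(protospacer)
  if (nchar(protospacer) != 20L) stop("protospacer must be 20 nt", call. = FALSE)
  if (nchar(pam) != 3L) stop("PAM must be 3 nt", call. = FALSE)
  if (ha5_interval[2] > cut_site) {
    stop("ha5_interval must end at or before cut_site", call. = FALSE)
  }
  if (ha3_interval[1] < cut_site) {
    stop("ha3_interval must start at or after cut_site", call. = FALSE)
  }
  structure(list(chrom = chrom, strand = strand, cut_site = as.integer(cut_site),
                 protospacer = protospacer, pam = pam,
                 ha5_interval = as.integer(ha5_interval),
                 ha3_interval = as.integer(ha3_interval)),
            class = "TargetLocus")
}

#' @export
print.TargetLocus <- function(x, ...) {
  cat(sprintf("TargetLocus %s:%d (%s)  guide %s  PAM %s\n", x$chrom,
              x$cut_site, x$strand, x$protospacer, x$pam))
  cat(sprintf("  HA5 [%d,%d)  HA3 [%d,%d)\n", x$ha5_interval[1],
              x$ha5_interval[2], x$ha3_interval[1], x$ha3_interval[2]))
  invisible(x)
}

## host-coordinate of guide/PAM offset `k` (0-based, 0..19 protospacer,
## 20..22 PAM), given the cut between protospacer bases 17/18
locus_offset_to_host <- function(locus, k) {
  if (locus$strand == "+") locus$cut_site - 17L + k else locus$cut_site + 16L - k
}

## protospacer+PAM as read on the guide strand, extracted from the host
locus_site_sequence <- function(locus, host) {
  host <- as_genome(host)
  chrom <- host[[locus$chrom]]
  if (locus$strand == "+") {
    substr(chrom, locus$cut_site - 17L + 1L, locus$cut_site + 6L)
  } else {
    revcomp(substr(chrom, locus$cut_site - 6L + 1L, locus$cut_site + 17L))
  }
}

#' Combine a host genome with the vector into one reference
#'
#' Host contigs keep their input order; the vector contig is appended last,
#' mirroring how a combined alignment reference is built by concatenating the
#' genome with the vector sequence.
#'
#' @param host named character vector or `DNAStringSet` of host contigs (may
#'   be empty)
#' @param vector a `VectorMap`
#' @return a `CombinedReference`: list with `contigs` (named character,
#'   vector last) and `vector_contig_name`
#' @export
build_combined_reference <- function(host, vector) {
  host <- as_genome(host)
  stopifnot(inherits(vector, "VectorMap"))
  if (vector$name %in% names(host)) {
    stop("duplicate-contig: host already has a contig named '", vector$name,
         "'", call. = FALSE)
  }
  contigs <- c(host, setNames(vector$sequence, vector$name))
  structure(list(contigs = contigs, vector_contig_name = vector$name),
            class = "CombinedReference")
}

#' @export
print.CombinedReference <- function(x, ...) {
  cat(sprintf("CombinedReference: %d contigs (vector = '%s')\n",
              length(x$contigs), x$vector_contig_name))
  for (nm in names(x$contigs)) {
    cat(sprintf("  %s  %d bp\n", nm, nchar(x$contigs[[nm]])))
  }
  invisible(x)
}

#' Write a combined reference to FASTA
#' @param ref a `CombinedReference`
#' @param path output FASTA path
#' @return `path`, invisibly
#' @export
write_combined_reference <- function(ref, path) {
  write_fasta(ref$contigs, path)
}

new_allele <- function(label, sequence, edits) {
  structure(list(label = label, sequence = sequence, edits = edits),
            class = "AlleleModel")
}

#' @export
print.AlleleModel <- function(x, ...) {
  cat(sprintf("AlleleModel %s (%d bp, %d edit%s)\n", x$label,
              nchar(x$sequence), length(x$edits),
              if (length(x$edits) == 1L) "" else "s"))
  invisible(x)
}

#' Wild-type allele at the targeted locus
#' @param locus a `TargetLocus`
#' @param host host genome (named character or `DNAStringSet`)
#' @return an `AlleleModel` with label `"WT"` and no edits
#' @export
build_wt_allele <- function(locus, host) {
  host <- as_genome(host)
  new_allele("WT", host[[locus$chrom]], list())
}

#' HDR knock-in allele: cDNA+polyA seamlessly integrated at the cut site
#'
#' The allele is the host chromosome with the span between the end of the 5'
#' homology region and the start of the 3' homology region replaced by
#' cDNA + polyA, then the donor's silent protospacer/PAM mutations applied.
#' No ITR sequence enters the allele (ITRs are not copied by HDR).
#'
#' @param locus a `TargetLocus`
#' @param host host genome
#' @param vector a `VectorMap`; its HA5/HA3 segments must match the host
#'   sequence at `locus$ha5_interval` / `locus$ha3_interval`
#' @param silent_mutations list of `c(offset, base)` pairs: 0-based offset
#'   into protospacer+PAM (0-19 protospacer, 20-22 PAM) and the replacement
#'   base as read on the guide strand. An empty list raises a warning (the
#'   knock-in allele would stay cleavable).
#' @return an `AlleleModel` with label `"HDR"`; attribute `insert_interval`
#'   holds the 0-based allele coordinates of the inserted cDNA+polyA
#' @export
build_hdr_allele <- function(locus, host, vector, silent_mutations = list()) {
  host <- as_genome(host)
  chrom <- host[[locus$chrom]]
  if (is.null(chrom)) stop("locus-mismatch: chrom not in host", call. = FALSE)
  ha5_host <- substr(chrom, locus$ha5_interval[1] + 1L, locus$ha5_interval[2])
  ha3_host <- substr(chrom, locus$ha3_interval[1] + 1L, locus$ha3_interval[2])
  if (!identical(ha5_host, vector_segment_seq(vector, "HA5")) ||
      !identical(ha3_host, vector_segment_seq(vector, "HA3"))) {
    stop("locus-mismatch: vector homology arms not found at the stated host ",
         "intervals", call. = FALSE)
  }
  if (length(silent_mutations) == 0L) {
    warning("no silent mutations: HDR allele protospacer remains cleavable")
  }
  insert <- paste0(vector_segment_seq(vector, "CDNA"),
                   vector_segment_seq(vector, "POLYA"))
  ha5_end <- locus$ha5_interval[2]
  ha3_start <- locus$ha3_interval[1]
  replaced <- substr(chrom, ha5_end + 1L, ha3_start)
  allele <- paste0(substr(chrom, 1L, ha5_end), insert,
                   substr(chrom, ha3_start + 1L, nchar(chrom)))
  shift <- nchar(insert) - (ha3_start - ha5_end)
  edits <- list(list(position = ha5_end, ref_span = replaced, alt_span = insert))
  for (m in silent_mutations) {
    k <- as.integer(m[[1]]); base <- toupper(m[[2]])
    if (k < 0L || k > 22L) {
      stop("silent mutation offset must lie in protospacer+PAM (0-22)",
           call. = FALSE)
    }
    h <- locus_offset_to_host(locus, k)
    base_host <- if (locus$strand == "+") base else revcomp(base)
    if (h < ha5_end) a <- h
    else if (h >= ha3_start) a <- h + shift
    else {
      warning("silent mutation at offset ", k,
              " falls in the span replaced by the insert; skipped")
      next
    }
    old <- substr(allele, a + 1L, a + 1L)
    if (identical(old, base_host)) {
      stop("silent mutation at offset ", k, " equals the reference base ",
           "(would not alter the protospacer)", call. = FALSE)
    }
    substr(allele, a + 1L, a + 1L) <- base_host
    edits[[length(edits) + 1L]] <- list(position = a, ref_span = old,
                                        alt_span = base_host)
  }
  out <- new_allele("HDR", allele, edits)
  attr(out, "insert_interval") <- c(ha5_end, ha5_end + nchar(insert))
  attr(out, "shift") <- shift
  out
}

#' NHEJ allele: a single indel near the cut site
#'
#' @param locus a `TargetLocus`
#' @param host host genome
#' @param indel list with `position` (0-based host coordinate, within 20 bp of
#'   the cut site), `ref_span` (bases deleted; must match the host) and
#'   `alt_span` (bases inserted); either span may be `""`
#' @return an `AlleleModel` with label `"NHEJ"`
#' @export
build_nhej_allele <- function(locus, host, indel) {
  host <- as_genome(host)
  chrom <- host[[locus$chrom]]
  pos <- as.integer(indel$position)
  ref_span <- toupper(indel$ref_span); alt_span <- toupper(indel$alt_span)
  if (abs(pos - locus$cut_site) > 20L) {
    stop("out-of-window: indel position must lie within 20 bp of the cut site",
         call. = FALSE)
  }
  if (nzchar(ref_span) &&
      !identical(substr(chrom, pos + 1L, pos + nchar(ref_span)), ref_span)) {
    stop("reference-mismatch: ref_span does not match the host at position ",
         pos, call. = FALSE)
  }
  allele <- paste0(substr(chrom, 1L, pos), alt_span,
                   substr(chrom, pos + nchar(ref_span) + 1L, nchar(chrom)))
  new_allele("NHEJ", allele,
             list(list(position = pos, ref_span = ref_span,
                       alt_span = alt_span)))
}
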