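# Aligned-fragment container: loading, duplicate removal, subsampling.
# A record is either a paired-end fragment interval (strand ".") that
# contributes both mate 5' ends, or a single stranded read (+/-).

#' Build a read set from a records table
#'
#' Records are deduplicated at fragment level: two records are duplicates
#' iff they share contig, start, end and strand (mirroring fragment-level
#' duplicate marking of paired-end data). The library size used for RPM
#' normalization is the post-deduplication read (mate) count: a strand "."
#' fragment counts as two mates, a stranded record as one.
#'
#' @param records Tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `strand` (`+`, `-` or `.`; default `.`).
#' @param contigs Named vector of contig lengths, or a named character
#'   vector of contig sequences.
#' @param read_length Mate length used when a fragment record must be
#'   expanded to reads (default 36).
#' @param dedup Remove duplicates (default `TRUE`).
#' @param source Free-text provenance tag.
#' @return Object of class `read_set`.
#' @export
read_set <- function(records, contigs, read_length = 36L, dedup = TRUE,
                     source = NA_character_) {
  contigs <- contig_lengths(contigs)
  records <- tibble::as_tibble(records)
  if (!"strand" %in% names(records)) records$strand <- "."
  records <- dplyr::select(records, "chrom", "start", "end", "strand")
  if (nrow(records) > 0) {
    if (!all(records$strand %in% c("+", "-", "."))) {
      abort("strand must be one of '+', '-', '.'")
    }
    check_contigs(records, contigs)
  }
  n_input <- nrow(records)
  if (dedup && n_input > 0) {
    records <- dplyr::distinct(records, .data$chrom, .data$start, .data$end,
                               .data$strand)
  }
  records <- dplyr::arrange(records, .data$chrom, .data$start, .data$end,
                            .data$strand)
  library_size <- sum(ifelse(records$strand == ".", 2L, 1L))
  structure(list(
    records = records, contigs = contigs,
    read_length = as.integer(read_length),
    n_input = n_input, n_duplicates_removed = n_input - nrow(records),
    library_size = library_size, source = source
  ), class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf(
    "<read_set> %d records (%d duplicates removed), library size %d reads, %d contig(s)\n",
    nrow(x$records), x$n_duplicates_removed, x$library_size,
    length(x$contigs)))
  invisible(x)
}

#' @rdname read_set
#' @param x A `read_set`.
#' @param ... Unused.
#' @exportS3Method
tidy.read_set <- function(x, ...) x$records

#' @rdname read_set
#' @exportS3Method
glance.read_set <- function(x, ...) {
  tibble::tibble(n_records = nrow(x$records), n_input = x$n_input,
                 n_duplicates_removed = x$n_duplicates_removed,
                 library_size = x$library_size,
                 n_contigs = length(x$contigs))
}

cigar_ref_length <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(0L)
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    if (!length(ops) || nchar(paste(ops, collapse = "")) != nchar(cg)) {
      abort(sprintf("malformed CIGAR string '%s'", cg))
    }
    n <- as.integer(sub("[MIDNSHP=X]", "", ops))
    op <- sub("\\d+", "", ops)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

parse_bed_records <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "track") & !startsWith(lines, "#")
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), strand = character()))
  }
  parts <- strsplit(lines, "\t")
  nf <- lengths(parts)
  bad <- which(nf < 3L)
  if (length(bad)) {
    abort(sprintf("malformed BED line %d: fewer than 3 fields", lineno[bad[1]]))
  }
  start <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    abort(sprintf("malformed BED line %d: non-numeric coordinates", lineno[bad[1]]))
  }
  strand <- vapply(seq_along(parts), function(i) {
    if (nf[i] >= 6L) parts[[i]][6L] else "."
  }, character(1))
  tibble::tibble(chrom = vapply(parts, `[[`, character(1), 1L),
                 start = start, end = end, strand = strand)
}

parse_sam_fragments <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    abort("reading SAM requires the Rsamtools package")
  }
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "isize"), flag = flag)
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  paired <- bitwAnd(rec$flag, 1L) > 0L
  out <- list()
  if (any(paired)) {
    first <- paired & rec$isize > 0L
    out$paired <- tibble::tibble(
      chrom = as.character(rec$rname[first]),
      start = rec$pos[first] - 1L,
      end = rec$pos[first] - 1L + rec$isize[first],
      strand = ".")
  }
  if (any(!paired)) {
    i <- which(!paired)
    reflen <- cigar_ref_length(rec$cigar[i])
    out$single <- tibble::tibble(
      chrom = as.character(rec$rname[i]),
      start = rec$pos[i] - 1L,
      end = rec$pos[i] - 1L + reflen,
      strand = ifelse(bitwAnd(rec$flag[i], 16L) > 0L, "-", "+"))
  }
  dplyr::bind_rows(out)
}

#' Load aligned fragments or reads from BED or SAM
#'
#' BED records with a strand field are treated as stranded reads; strand
#' "." (or absent) records as paired-end fragment intervals. SAM input is
#' converted and filtered (unmapped, secondary and supplementary records
#' excluded); proper pairs are collapsed to fragment intervals via the
#' template length. Duplicates (identical contig, start, end, strand) are
#' removed.
#'
#' @param path Input path.
#' @param contigs Named vector of contig lengths or contig sequences.
#' @param format `"auto"` (by extension), `"bed"` or `"sam"`.
#' @param read_length Mate length for fragment expansion (default 36).
#' @param dedup Remove duplicates (default `TRUE`).
#' @return A [read_set()].
#' @export
load_alignments <- function(path, contigs, format = c("auto", "bed", "sam"),
                            read_length = 36L, dedup = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam" else "bed"
  }
  records <- switch(format,
                    bed = parse_bed_records(path),
                    sam = parse_sam_fragments(path))
  read_set(records, contigs, read_length = read_length, dedup = dedup,
           source = path)
}

#' Subsample a read set
#'
#' Keeps each record independently with probability `fraction` (seeded);
#' `fraction = 1` returns the input unchanged.
#'
#' @param reads A [read_set()].
#' @param fraction Keep probability in (0, 1].
#' @param seed Integer seed.
#' @return A [read_set()] with updated library size.
#' @export
subsample <- function(reads, fraction, seed = 1L) {
  stopifnot(inherits(reads, "read_set"))
  if (!is_scalar_number(fraction) || fraction <= 0 || fraction > 1) {
    abort("fraction must be in (0, 1]")
  }
  if (fraction == 1) return(reads)
  keep <- withr::with_seed(seed, runif(nrow(reads$records)) < fraction)
  read_set(reads$records[keep, ], reads$contigs,
           read_length = reads$read_length, dedup = FALSE,
           source = reads$source)
}

# Expand records to mate-level read intervals (strand "." fragments give
# two mates of read_length, clipped to the fragment).
expand_to_reads <- function(reads) {
  rec <- reads$records
  frag <- rec$strand == "."
  parts <- list(rec[!frag, c("chrom", "start", "end", "strand")])
  if (any(frag)) {
    fr <- rec[frag, ]
    rl <- pmin(reads$read_length, fr$end - fr$start)
    parts$p <- tibble::tibble(chrom = fr$chrom, start = fr$start,
                              end = fr$start + rl, strand = "+")
    parts$m <- tibble::tibble(chrom = fr$chrom, start = fr$end - rl,
                              end = fr$end, strand = "-")
  }
  dplyr::bind_rows(parts)
}
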