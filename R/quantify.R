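# Quantitative read-outs: windowed occupancy (RPM_OT), treatment-minus-
# control occupancy (RPM_diff), the cutting score (C-score: product of
# plus- and minus-strand 5'-end RPM profiles summed over a running 3-bp
# window), cut-vs-bind classification, replicate agreement, subsampling
# saturation, and amplicon indel frequency.

#' Windowed occupancy (RPM) around predicted cut sites
#'
#' Counts reads (mates) whose interval overlaps `[cut - flank,
#' cut + flank + 1)` and divides by `library_size / 1e6` — the traditional
#' RPM formula applied to the +/- `flank` bp window around each site.
#' Fragment records contribute their two mates. Windows are clipped at
#' contig edges with a warning.
#'
#' @param reads A [read_set()].
#' @param sites A `caskas_sites` tibble, or a tibble with `chrom` and
#'   `cut_site` columns.
#' @param flank Half-width of the window (default 500).
#' @return Numeric vector of RPM values, one per site.
#' @export
rpm_ot <- function(reads, sites, flank = 500L) {
  stopifnot(inherits(reads, "read_set"))
  if (reads$library_size == 0) abort("library size is zero")
  mates <- expand_to_reads(reads)
  out <- numeric(nrow(sites))
  for (chrom in unique(sites$chrom)) {
    si <- which(sites$chrom == chrom)
    m <- mates[mates$chrom == chrom, ]
    clen <- reads$contigs[[chrom]]
    if (is.null(clen) || is.na(clen)) {
      abort(sprintf("contig %s absent from read set", chrom))
    }
    ws <- sites$cut_site[si] - flank
    we <- sites$cut_site[si] + flank + 1L
    if (any(ws < 0 | we > clen)) {
      warn(sprintf("quantification window clipped at %s contig edge", chrom))
      ws <- pmax(0L, ws); we <- pmin(as.integer(clen), we)
    }
    if (nrow(m) == 0) next
    ss <- sort(m$start)
    ee <- sort(m$end)
    n <- nrow(m)
    # overlap iff read start < window end and read end > window start
    n_start_ge <- n - findInterval(we - 1L, ss)       # starts >= we
    n_end_le <- findInterval(ws, ee)                  # ends <= ws
    out[si] <- (n - n_start_ge - n_end_le) * 1e6 / reads$library_size
  }
  out
}

#' Treatment-minus-control occupancy (RPM difference)
#'
#' The in vivo occupancy estimate: RPM in the site window for the guide
#' library minus RPM in the matched no-guide control. May be negative.
#'
#' @param treatment,control [read_set()] objects (both non-empty).
#' @inheritParams rpm_ot
#' @return Numeric vector of RPM differences, one per site.
#' @export
rpm_diff <- function(treatment, control, sites, flank = 500L) {
  if (treatment$library_size == 0 || control$library_size == 0) {
    abort("both treatment and control libraries must be non-empty")
  }
  rpm_ot(treatment, sites, flank) - rpm_ot(control, sites, flank)
}

rolling3 <- function(v) {
  n <- length(v)
  if (n == 0) return(v)
  out <- v
  if (n > 1) {
    out <- out + c(v[-1], 0) + c(0, v[-n])
  }
  out
}

#' Cutting-score track
#'
#' At each position i the C-score is the product of the plus-strand and
#' minus-strand 5'-end RPM masses each summed over the running 3-bp window
#' `[i - 1, i + 1]` (truncated at contig edges). The score is high only
#' where read 5' ends phase on both strands, i.e. at cleavage sites; pure
#' binding spreads 5' ends and keeps the product low.
#'
#' @param fiveprime A `caskas_profile` of kind `"fiveprime"`.
#' @return Object of class `c_score_track`: per-contig numeric vectors,
#'   with the window size recorded.
#' @export
c_score_track <- function(fiveprime) {
  stopifnot(inherits(fiveprime, "caskas_profile"))
  if (fiveprime$kind != "fiveprime") {
    abort("c_score_track requires a 5'-end profile")
  }
  values <- lapply(fiveprime$values, function(v) {
    rolling3(v$plus) * rolling3(v$minus)
  })
  structure(list(values = values, contigs = fiveprime$contigs, window = 3L,
                 library_size = fiveprime$library_size),
            class = "c_score_track")
}

#' @export
print.c_score_track <- function(x, ...) {
  mx <- max(vapply(x$values, function(v) if (length(v)) max(v) else 0, numeric(1)))
  cat(sprintf("<c_score_track> %d contig(s), 3-bp window, max %.3g\n",
              length(x$values), mx))
  invisible(x)
}

#' @exportS3Method
tidy.c_score_track <- function(x, drop_zero = TRUE, ...) {
  purrr::map_dfr(names(x$values), function(chrom) {
    v <- x$values[[chrom]]
    out <- tibble::tibble(chrom = chrom, pos = seq_along(v) - 1L, c_score = v)
    if (drop_zero) out <- out[out$c_score != 0, ]
    out
  })
}

#' Classify sites as cut versus bind-only from the C-score
#'
#' For each site the maximal C-score within +/- `window` of the predicted
#' cut is compared to an empirical null obtained by permuting the per-base
#' plus- and minus-strand 5'-end masses within the same window (which
#' preserves both strands' total mass, i.e. is occupancy-matched by
#' construction, while destroying the cleavage phasing). A site is called
#' `cut` when its observed maximum exceeds the configured quantile of the
#' null maxima, `bind_only` otherwise, and `undetermined` when its windowed
#' occupancy is below `min_rpm`.
#'
#' @param reads A [read_set()] (for the occupancy floor).
#' @param fiveprime The 5'-end profile of the same read set.
#' @param sites Sites with `chrom` and `cut_site`.
#' @param window Half-width of the search window around the cut (default 50).
#' @param n_perm Number of permutations for the null (default 2000).
#' @param null_quantile Null quantile above which a site is called cut
#'   (default 0.999).
#' @param min_rpm Occupancy floor below which the call is `undetermined`.
#' @param flank Occupancy window half-width (default 500).
#' @param seed Seed for the permutation null.
#' @return Tibble: `rpm_ot`, `c_score_max`, `c_score_pos`, `null_cutoff`,
#'   `cut_call`, one row per site.
#' @export
classify_cut_vs_bind <- function(reads, fiveprime, sites, window = 50L,
                                 n_perm = 2000L, null_quantile = 0.999,
                                 min_rpm = 1, flank = 500L, seed = 1L) {
  stopifnot(inherits(fiveprime, "caskas_profile"))
  if (n_perm < 1) abort("n_perm must be positive")
  occ <- rpm_ot(reads, sites, flank)
  n <- nrow(sites)
  c_max <- numeric(n); c_pos <- integer(n); cutoff <- numeric(n)
  call <- character(n)
  cs <- c_score_track(fiveprime)
  for (i in seq_len(n)) {
    chrom <- sites$chrom[i]
    cut <- sites$cut_site[i]
    len <- length(cs$values[[chrom]])
    a <- max(0L, cut - window)
    b <- min(len - 1L, cut + window)
    seg <- cs$values[[chrom]][(a + 1L):(b + 1L)]
    c_max[i] <- max(seg)
    c_pos[i] <- a + which.max(seg) - 1L
    if (occ[i] < min_rpm) {
      call[i] <- "undetermined"
      cutoff[i] <- NA_real_
      next
    }
    # permutation null: shuffle the raw per-strand 5' masses in a window
    # padded by 1 bp so truncated 3-bp sums at the edges are honest
    pa <- max(0L, a - 1L); pb <- min(len - 1L, b + 1L)
    vp <- fiveprime$values[[chrom]]$plus[(pa + 1L):(pb + 1L)]
    vm <- fiveprime$values[[chrom]]$minus[(pa + 1L):(pb + 1L)]
    null_max <- withr::with_seed(derive_seed(seed, i), {
      vapply(seq_len(n_perm), function(p) {
        sp <- rolling3(sample(vp))
        sm <- rolling3(sample(vm))
        max(sp * sm)
      }, numeric(1))
    })
    cutoff[i] <- quantile(null_max, null_quantile, names = FALSE, type = 1)
    call[i] <- if (c_max[i] > cutoff[i]) "cut" else "bind_only"
  }
  tibble::tibble(rpm_ot = occ, c_score_max = c_max, c_score_pos = c_pos,
                 null_cutoff = cutoff, cut_call = call)
}

#' Replicate agreement of per-site occupancy
#'
#' @param a,b Numeric vectors of matched per-site quantifications (e.g.
#'   `rpm_ot` over the same site list), length >= 3.
#' @return Object of class `replicate_agreement` with Pearson and Spearman
#'   correlations and the paired table.
#' @export
replicate_agreement <- function(a, b) {
  if (length(a) != length(b)) abort("replicate vectors must be matched")
  if (length(a) < 3) abort("need at least 3 matched sites")
  structure(list(
    pearson = cor(a, b, method = "pearson"),
    spearman = cor(a, b, method = "spearman"),
    pairs = tibble::tibble(replicate_a = a, replicate_b = b)
  ), class = "replicate_agreement")
}

#' @export
print.replicate_agreement <- function(x, ...) {
  cat(sprintf("<replicate_agreement> %d sites: Pearson %.3f, Spearman %.3f\n",
              nrow(x$pairs), x$pearson, x$spearman))
  invisible(x)
}

#' @exportS3Method
tidy.replicate_agreement <- function(x, ...) x$pairs

#' @exportS3Method
glance.replicate_agreement <- function(x, ...) {
  tibble::tibble(n_sites = nrow(x$pairs), pearson = x$pearson,
                 spearman = x$spearman)
}

#' Sequencing-depth saturation of per-site quantification
#'
#' For each subsampling fraction, draws `n_sets` seeded subsamples,
#' recomputes the windowed occupancy of every site, and reports the mean
#' and SD (over sets) of the proportion of sites whose subsampled value is
#' within `tolerance` (relative) of the full-depth value. Sites with zero
#' full-depth occupancy are excluded from the proportion (relative
#' tolerance undefined) and counted.
#'
#' @param reads A [read_set()].
#' @param sites Sites with `chrom` and `cut_site`.
#' @param fractions Subsampling fractions in (0, 1]; include 1.0 to anchor
#'   the proportion at exactly 1.
#' @param n_sets Subsample sets per fraction (default 10).
#' @param tolerance Relative tolerance (default 0.2).
#' @param flank Occupancy window half-width.
#' @param seed Master seed.
#' @return Object of class `saturation_result`: per-fraction tibble of mean
#'   and SD plus bookkeeping fields.
#' @export
saturation_analysis <- function(reads, sites, fractions = c(0.05, 0.1, 0.2,
                                                            0.35, 0.5, 0.75, 1),
                                n_sets = 10L, tolerance = 0.2, flank = 500L,
                                seed = 1L) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  full <- rpm_ot(reads, sites, flank)
  usable <- full > 0
  n_zero <- sum(!usable)
  if (!any(usable)) abort("all sites have zero full-depth occupancy")
  per_fraction <- purrr::map_dfr(seq_along(fractions), function(fi) {
    f <- fractions[fi]
    props <- vapply(seq_len(n_sets), function(s) {
      sub <- subsample(reads, f, derive_seed(seed, fi * 1000 + s))
      v <- rpm_ot(sub, sites, flank)
      mean(abs(v[usable] - full[usable]) <= tolerance * full[usable])
    }, numeric(1))
    tibble::tibble(fraction = f, mean_within = mean(props),
                   sd_within = sd(props), n_sets = n_sets)
  })
  structure(list(table = per_fraction, tolerance = tolerance,
                 n_sites = sum(usable), n_zero_excluded = n_zero,
                 flank = flank, seed = seed),
            class = "saturation_result")
}

#' @export
print.saturation_result <- function(x, ...) {
  cat(sprintf("<saturation_result> %d sites (%d zero-occupancy excluded), tolerance %.0f%%\n",
              x$n_sites, x$n_zero_excluded, 100 * x$tolerance))
  print(x$table)
  invisible(x)
}

#' @exportS3Method
tidy.saturation_result <- function(x, ...) x$table

#' @exportS3Method
glance.saturation_result <- function(x, ...) {
  tibble::tibble(n_sites = x$n_sites, n_zero_excluded = x$n_zero_excluded,
                 tolerance = x$tolerance,
                 n_fractions = nrow(x$table),
                 mean_at_full = x$table$mean_within[x$table$fraction == 1][1])
}

# ---- amplicon indel quantification ----------------------------------------

#' Per-position indel frequency from amplicon alignments
#'
#' A read "contains an indel over position p" iff a deletion in its
#' alignment spans p, or an insertion occurs between p and p + 1 (the
#' insertion is assigned to the reference base 5' of the insertion point).
#' The frequency at p is the number of such reads divided by the number of
#' reads whose alignment spans p.
#'
#' @param alignments Either a path to a SAM file or a tibble with columns
#'   `chrom`, `pos` (1-based leftmost mapped position, as in SAM) and
#'   `cigar`.
#' @param region Optional list/tibble with `chrom`, `start`, `end`
#'   (0-based half-open) restricting the report.
#' @return Object of class `indel_profile`: tibble with `chrom`, `pos`
#'   (0-based), `depth`, `indel_reads`, `frequency`.
#' @export
indel_frequency <- function(alignments, region = NULL) {
  if (is.character(alignments)) {
    alignments <- read_sam_cigar(alignments)
  }
  aln <- tibble::as_tibble(alignments)
  stopifnot(all(c("chrom", "pos", "cigar") %in% names(aln)))
  res <- purrr::map_dfr(unique(aln$chrom), function(chrom) {
    a <- aln[aln$chrom == chrom, ]
    reflen <- cigar_ref_length(a$cigar)
    lo <- min(a$pos) - 1L
    hi <- max(a$pos - 1L + reflen)
    nbin <- hi - lo
    depth <- numeric(nbin)
    indel <- numeric(nbin)
    for (i in seq_len(nrow(a))) {
      ref0 <- a$pos[i] - 1L  # 0-based current reference coordinate
      ops <- regmatches(a$cigar[i], gregexpr("\\d+[MIDNSHP=X]", a$cigar[i]))[[1]]
      if (!length(ops)) abort(sprintf("malformed CIGAR in record %d", i))
      has <- logical(nbin)
      span_s <- ref0
      for (op in ops) {
        n <- as.integer(sub(".$", "", op))
        code <- substring(op, nchar(op))
        if (code %in% c("M", "=", "X")) {
          ref0 <- ref0 + n
        } else if (code %in% c("D", "N")) {
          if (code == "D") has[(ref0 - lo + 1L):(ref0 - lo + n)] <- TRUE
          ref0 <- ref0 + n
        } else if (code == "I") {
          if (ref0 > span_s) has[ref0 - lo] <- TRUE  # base 5' of insertion
        }
        # S, H, P consume no reference
      }
      span <- (span_s - lo + 1L):(ref0 - lo)
      depth[span] <- depth[span] + 1
      indel <- indel + has
    }
    tibble::tibble(chrom = chrom, pos = seq(lo, hi - 1L), depth = depth,
                   indel_reads = indel,
                   frequency = ifelse(depth > 0, indel / depth, NA_real_))
  })
  if (!is.null(region)) {
    res <- res[res$chrom == region$chrom & res$pos >= region$start &
                 res$pos < region$end, ]
  }
  class(res) <- c("indel_profile", class(res))
  res
}

#' Read mapped SAM records (chrom, pos, cigar) for indel analysis
#' @param path SAM path.
#' @return Tibble with `chrom`, `pos`, `cigar`.
#' @export
read_sam_cigar <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    abort("reading SAM requires the Rsamtools package")
  }
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE)
  p <- Rsamtools::ScanBamParam(what = c("rname", "pos", "cigar"), flag = flag)
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  tibble::tibble(chrom = as.character(rec$rname), pos = rec$pos,
                 cigar = rec$cigar)
}
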