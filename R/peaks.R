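# De novo peak calling with a local-lambda Poisson model, blacklist
# filtering, and a quantitative strand-asymmetry curation score that
# formalizes the canonical "plus-strand reads left, minus-strand reads
# right of the occupied site" shape.

new_peaks_tibble <- function(df) {
  df <- tibble::as_tibble(df)
  class(df) <- c("caskas_peaks", class(df))
  df
}

empty_peaks <- function() {
  new_peaks_tibble(tibble::tibble(
    chrom = character(), start = integer(), end = integer(),
    summit = integer(), n_windows = integer(), count = integer(),
    fold_enrichment = numeric(), p_value = numeric(), q_value = numeric()
  ))
}

#' Score sliding windows under the local-lambda Poisson model
#'
#' Windows are scored by the Poisson upper-tail probability of their
#' record-start count against the most conservative of the global rate and
#' the local rates estimated in centered flanks (1 kb / 5 kb / 10 kb by
#' default), all scaled to the window width. Benjamini-Hochberg correction
#' is applied across all windows genome-wide.
#'
#' @param reads A [read_set()].
#' @param window Window width in bp (>= 10).
#' @param step Step between window starts.
#' @param flanks Flank widths for local background estimation.
#' @return Tibble with one row per window: `chrom`, `start`, `end`,
#'   `count`, `lambda`, `p_value`, `q_value`.
#' @export
score_windows <- function(reads, window = 300L, step = 100L,
                          flanks = c(1000L, 5000L, 10000L)) {
  stopifnot(inherits(reads, "read_set"))
  if (window < 10L) abort("window must be at least 10 bp")
  if (reads$library_size == 0) abort("read set is empty")
  total_records <- nrow(reads$records)
  genome_len <- sum(reads$contigs)
  global_rate <- total_records / genome_len  # records per bp

  res <- purrr::map_dfr(names(reads$contigs), function(chrom) {
    len <- as.integer(reads$contigs[[chrom]])
    if (len < window) return(NULL)
    r <- reads$records[reads$records$chrom == chrom, ]
    csum <- c(0, cumsum(tabulate(r$start + 1L, nbins = len)))
    wstart <- seq(0L, len - window, by = step)
    cnt <- csum[wstart + window + 1L] - csum[wstart + 1L]
    lambda <- rep(global_rate * window, length(wstart))
    center <- wstart + window %/% 2L
    for (fl in flanks) {
      a <- pmax(0L, center - fl %/% 2L)
      b <- pmin(len, center + fl %/% 2L)
      loc <- (csum[b + 1L] - csum[a + 1L]) / (b - a) * window
      lambda <- pmax(lambda, loc)
    }
    tibble::tibble(chrom = chrom, start = wstart,
                   end = wstart + window, count = as.integer(cnt),
                   lambda = lambda,
                   p_value = ppois(cnt - 1, lambda, lower.tail = FALSE))
  })
  res$q_value <- p.adjust(res$p_value, method = "BH")
  res
}

#' Call enriched peaks from a read set
#'
#' Significant windows (`q <= min_q`, nonzero count) are merged when they
#' overlap or abut; the summit of each merged region is the position of
#' maximal combined fragment coverage (first position on ties). Fold
#' enrichment is the maximum count/lambda over member windows;
#' `p_value`/`q_value` are the member minima. Deterministic.
#'
#' @inheritParams score_windows
#' @param min_q Significance threshold on BH-adjusted window p-values.
#' @return A `caskas_peaks` tibble: `chrom`, `start`, `end`, `summit`,
#'   `n_windows`, `count`, `fold_enrichment`, `p_value`, `q_value`.
#' @export
call_peaks <- function(reads, window = 300L, step = 100L, min_q = 0.01,
                       flanks = c(1000L, 5000L, 10000L)) {
  w <- score_windows(reads, window, step, flanks)
  sig <- w[w$q_value <= min_q & w$count > 0, ]
  if (nrow(sig) == 0) return(empty_peaks())

  peaks <- purrr::map_dfr(unique(sig$chrom), function(chrom) {
    s <- sig[sig$chrom == chrom, ]
    s <- s[order(s$start), ]
    grp <- cumsum(c(1L, as.integer(s$start[-1] > head(s$end, -1))))
    len <- as.integer(reads$contigs[[chrom]])
    r <- reads$records[reads$records$chrom == chrom, ]
    cov <- interval_coverage(r$start, r$end, len)
    purrr::map_dfr(split(s, grp), function(g) {
      a <- min(g$start); b <- max(g$end)
      region <- cov[(a + 1L):b]
      tibble::tibble(
        chrom = chrom, start = a, end = b,
        summit = a + which.max(region) - 1L,
        n_windows = nrow(g), count = max(g$count),
        fold_enrichment = max(g$count / g$lambda),
        p_value = min(g$p_value), q_value = min(g$q_value))
    })
  })
  new_peaks_tibble(dplyr::arrange(peaks, .data$chrom, .data$start))
}

#' Remove peaks overlapping blacklisted regions
#'
#' A peak is removed if its interval overlaps any blacklist interval by at
#' least 1 bp. The number of removed peaks is attached as attribute
#' `n_removed`.
#'
#' @param peaks A `caskas_peaks` tibble.
#' @param blacklist Tibble with `chrom`, `start`, `end` (0-based
#'   half-open), e.g. from [read_bed_intervals()].
#' @return Filtered peaks.
#' @export
filter_blacklist <- function(peaks, blacklist) {
  if (nrow(peaks) == 0 || is.null(blacklist) || nrow(blacklist) == 0) {
    attr(peaks, "n_removed") <- 0L
    return(peaks)
  }
  hit <- rep(FALSE, nrow(peaks))
  for (chrom in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == chrom)
    bl <- blacklist[blacklist$chrom == chrom, ]
    if (nrow(bl) == 0) next
    q <- IRanges::IRanges(start = peaks$start[pi] + 1L, end = peaks$end[pi])
    s <- IRanges::IRanges(start = bl$start + 1L, end = bl$end)
    hit[pi] <- IRanges::countOverlaps(q, s) > 0
  }
  out <- peaks[!hit, ]
  attr(out, "n_removed") <- sum(hit)
  out
}

#' Read plain BED intervals (e.g. a blacklist)
#' @param path BED path.
#' @return Tibble with `chrom`, `start`, `end`.
#' @export
read_bed_intervals <- function(path) {
  parse_bed_records(path)[, c("chrom", "start", "end")]
}

#' Strand-asymmetry score of a candidate occupancy site
#'
#' For an anchor position p, let `Lp`/`Rp` be the plus-strand 5'-end mass in
#' `[p - half_window, p)` / `[p, p + half_window)` and `Lm`/`Rm` the
#' analogous minus-strand masses. The score at p is
#' `(Lp + Rm - Rp - Lm) / (Lp + Rp + Lm + Rm)`, which is 1 when all plus
#' mass lies left of p and all minus mass right of it, 0 for a
#' strand-symmetric pileup, and is negated by swapping the strands. The
#' anchor is scanned across `[start, end]` and the maximum is returned.
#'
#' @param fiveprime A `caskas_profile` of kind `"fiveprime"`.
#' @param chrom,start,end Region to scan (0-based half-open).
#' @param half_window Half-window in bp (>= 25).
#' @return One-row tibble: `score` (NA if every anchor has zero mass),
#'   `anchor`, `scored`.
#' @export
asymmetry_score <- function(fiveprime, chrom, start, end, half_window = 100L) {
  stopifnot(inherits(fiveprime, "caskas_profile"))
  if (half_window < 25L) abort("half_window must be at least 25 bp")
  v <- fiveprime$values[[chrom]]
  if (is.null(v)) abort(sprintf("contig %s not in profile", chrom))
  len <- length(v$plus)
  cp <- c(0, cumsum(v$plus))
  cm <- c(0, cumsum(v$minus))
  wsum <- function(cs, a, b) {  # mass over [a, b), clipped
    a <- pmax(0L, a); b <- pmin(len, b)
    bad <- a >= b
    out <- cs[pmax(b, a) + 1L] - cs[a + 1L]
    out[bad] <- 0
    out
  }
  p <- seq.int(max(0L, start), min(len, end))
  Lp <- wsum(cp, p - half_window, p)
  Rp <- wsum(cp, p, p + half_window)
  Lm <- wsum(cm, p - half_window, p)
  Rm <- wsum(cm, p, p + half_window)
  tot <- Lp + Rp + Lm + Rm
  score <- ifelse(tot > 0, (Lp + Rm - Rp - Lm) / tot, NA_real_)
  if (all(is.na(score))) {
    return(tibble::tibble(score = NA_real_, anchor = NA_integer_,
                          scored = FALSE))
  }
  best <- which.max(score)
  tibble::tibble(score = score[best], anchor = p[best], scored = TRUE)
}

#' Apply asymmetry-based curation to a peak set
#'
#' Scores every peak with [asymmetry_score()] and flags peaks passing the
#' canonical-shape threshold. Peaks with zero 5'-end mass in every anchor
#' window are flagged unscored and fail curation.
#'
#' @param peaks A `caskas_peaks` tibble.
#' @param fiveprime A 5'-end `caskas_profile`.
#' @param half_window Half-window passed to [asymmetry_score()].
#' @param threshold Curation threshold on the score (default 0.5).
#' @return Peaks with `asymmetry`, `anchor`, `scored`, `curation_pass`
#'   columns added.
#' @export
curate_peaks <- function(peaks, fiveprime, half_window = 100L,
                         threshold = 0.5) {
  if (nrow(peaks) == 0) {
    peaks$asymmetry <- numeric(); peaks$anchor <- integer()
    peaks$scored <- logical(); peaks$curation_pass <- logical()
    return(peaks)
  }
  sc <- purrr::map_dfr(seq_len(nrow(peaks)), function(i) {
    asymmetry_score(fiveprime, peaks$chrom[i], peaks$start[i], peaks$end[i],
                    half_window)
  })
  peaks$asymmetry <- sc$score
  peaks$anchor <- sc$anchor
  peaks$scored <- sc$scored
  peaks$curation_pass <- !is.na(sc$score) & sc$score >= threshold
  peaks
}

#' Annotate peaks against predicted target sites
#'
#' Each peak is annotated with the predicted site whose cut coordinate lies
#' within `max_distance` of the summit; among candidates the nearest wins,
#' with distance ties broken by fewer mismatches, then by coordinate.
#' Peaks with no candidate are `novel`. Idempotent and order-independent.
#'
#' @param peaks A `caskas_peaks` tibble (with `summit`).
#' @param sites A `caskas_sites` tibble with `cut_site`.
#' @param max_distance Maximum summit-to-cut distance (default 500 bp,
#'   matching the occupancy quantification window).
#' @return Peaks with `annotation` (`predicted_site`/`novel`),
#'   `site_guide`, `site_cut`, `site_mismatches`, `site_distance` columns;
#'   attributes `n_predicted` and `n_novel`.
#' @export
annotate_peaks <- function(peaks, sites, max_distance = 500L) {
  n <- nrow(peaks)
  ann <- tibble::tibble(annotation = rep("novel", n),
                        site_guide = NA_character_,
                        site_cut = NA_integer_,
                        site_mismatches = NA_integer_,
                        site_distance = NA_integer_)
  if (n > 0 && nrow(sites) > 0) {
    for (i in seq_len(n)) {
      cand <- sites[sites$chrom == peaks$chrom[i], ]
      if (nrow(cand) == 0) next
      d <- abs(cand$cut_site - peaks$summit[i])
      cand <- cand[d <= max_distance, ]
      d <- d[d <= max_distance]
      if (nrow(cand) == 0) next
      ord <- order(d, cand$n_mismatches, cand$cut_site)
      best <- cand[ord[1], ]
      ann$annotation[i] <- "predicted_site"
      ann$site_guide[i] <- best$guide
      ann$site_cut[i] <- best$cut_site
      ann$site_mismatches[i] <- best$n_mismatches
      ann$site_distance[i] <- d[ord[1]]
    }
  }
  out <- dplyr::bind_cols(
    peaks[, setdiff(names(peaks), names(ann))], ann)
  out <- new_peaks_tibble(out)
  attr(out, "n_predicted") <- sum(ann$annotation == "predicted_site")
  attr(out, "n_novel") <- sum(ann$annotation == "novel")
  out
}

#' Write peaks as BED6
#' @param peaks A `caskas_peaks` tibble.
#' @param path Output path.
#' @export
write_peaks_bed <- function(peaks, path) {
  bed <- tibble::tibble(
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    name = sprintf("peak_%d|summit=%d", seq_len(nrow(peaks)), peaks$summit),
    score = pmin(1000L, as.integer(round(10 * peaks$fold_enrichment))),
    strand = ".")
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
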