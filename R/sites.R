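# Off-target protospacer search: ungapped mismatch scan and single-bulge
# gapped scan. Coordinates are 0-based half-open throughout; mismatch and
# bulge offsets are counted from the PAM-proximal end (1 = adjacent to PAM).

new_sites_tibble <- function(df) {
  df <- tibble::as_tibble(df)
  class(df) <- c("caskas_sites", class(df))
  df
}

empty_sites <- function() {
  new_sites_tibble(tibble::tibble(
    guide = character(), chrom = character(), start = integer(),
    end = integer(), strand = character(), pam_start = integer(),
    pam_end = integer(), site_sequence = character(),
    n_mismatches = integer(), mismatch_offsets = list(),
    bulge_type = character(), bulge_size = integer(),
    bulge_offset = integer(), cut_site = integer()
  ))
}

#' Find protospacer matches for a guide in a genome
#'
#' Scans both strands of every contig for exact PAM occurrences and reports
#' each adjacent protospacer whose alignment to the spacer stays within the
#' mismatch and bulge budgets. With `max_bulge = 0` the search is a pure
#' substitution scan and every qualifying site is reported. With
#' `max_bulge > 0`, each PAM locus is aligned to the spacer allowing at most
#' one contiguous bulge (a run of extra genomic bases, "DNA bulge", or of
#' skipped spacer bases, "RNA bulge") of at most `max_bulge` bases, and the
#' minimal-cost alignment per PAM locus is reported. Cost is ordered
#' lexicographically by (bulged bases, mismatches); remaining ties prefer a
#' DNA bulge over an RNA bulge and a bulge placed closer to the PAM.
#'
#' Genomic `N` (or any non-ACGT base) never matches a spacer base and never
#' satisfies a PAM position. The PAM itself must match exactly (IUPAC codes
#' expand; no PAM mismatches are allowed).
#'
#' @param genome Named character vector of contig sequences (uppercase or
#'   lowercase ACGTN).
#' @param guide A [guide_rna()].
#' @param max_mismatches Maximum substitutions in the protospacer.
#' @param max_bulge Maximum bulged bases (one contiguous bulge per site).
#' @return A `caskas_sites` tibble sorted by (chrom, start, strand): columns
#'   `guide`, `chrom`, `start`, `end`, `strand`, `pam_start`, `pam_end`,
#'   `site_sequence` (protospacer-strand orientation), `n_mismatches`,
#'   `mismatch_offsets` (list column, distances from the PAM), `bulge_type`
#'   (`none`/`dna`/`rna`), `bulge_size`, `bulge_offset`, `cut_site` (blunt
#'   cut coordinate, see [predicted_cut_site()]).
#' @examples
#' g <- guide_rna("sg1", "GCTTAATTAAGGTAAACGTC")
#' genome <- c(chr1 = paste0(strrep("A", 50), "GCTTAATTAAGGTAAACGTCAGG", strrep("T", 50)))
#' find_sites(genome, g, max_mismatches = 0)
#' @export
find_sites <- function(genome, guide, max_mismatches = 4L, max_bulge = 0L) {
  stopifnot(inherits(guide, "guide_rna"), max_mismatches >= 0, max_bulge >= 0)
  if (is.null(names(genome)) || any(!nzchar(names(genome)))) {
    abort("genome must be a named character vector of contigs")
  }
  pam_sets <- pam_position_sets(guide$pam)
  res <- purrr::map(names(genome), function(chrom) {
    seq_fwd <- toupper(genome[[chrom]])
    if (max_bulge == 0L) {
      scan_contig_mismatch(chrom, seq_fwd, guide, pam_sets, max_mismatches)
    } else {
      scan_contig_bulged(chrom, seq_fwd, guide, pam_sets, max_mismatches,
                         as.integer(max_bulge))
    }
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0L) return(empty_sites())
  out <- dplyr::arrange(out, .data$chrom, .data$start, .data$strand)
  new_sites_tibble(out)
}

# ---- ungapped scan ---------------------------------------------------------

scan_strand_mismatch <- function(code, spacer_code, pam_sets, max_mm) {
  L <- length(spacer_code)
  P <- length(pam_sets)
  n <- length(code)
  n_start <- n - L - P + 1L
  if (n_start < 1L) {
    return(list(start = integer(), n_mm = integer(), offsets = list()))
  }
  ok <- rep(TRUE, n_start)
  for (k in seq_len(P)) {
    ok <- ok & pam_sets[[k]][code[(L + k):(L + k + n_start - 1L)] + 1L]
  }
  starts <- which(ok)
  if (!length(starts)) {
    return(list(start = integer(), n_mm = integer(), offsets = list()))
  }
  mm_mat <- matrix(FALSE, length(starts), L)
  for (j in seq_len(L)) {
    mm_mat[, j] <- code[starts + j - 1L] != spacer_code[j]
  }
  n_mm <- as.integer(rowSums(mm_mat))
  keep <- n_mm <= max_mm
  starts <- starts[keep]
  mm_mat <- mm_mat[keep, , drop = FALSE]
  n_mm <- n_mm[keep]
  # offset from PAM of 5'->3' spacer position j is L - j + 1
  offsets <- lapply(seq_along(starts), function(i) {
    js <- which(mm_mat[i, ])
    sort(L - js + 1L)
  })
  list(start = starts, n_mm = n_mm, offsets = offsets)
}

scan_contig_mismatch <- function(chrom, seq_fwd, guide, pam_sets, max_mm) {
  L <- nchar(guide$spacer)
  P <- nchar(guide$pam)
  spacer_code <- encode_seq(guide$spacer)
  code_fwd <- encode_seq(seq_fwd)
  n <- length(code_fwd)
  rows <- list()

  fwd <- scan_strand_mismatch(code_fwd, spacer_code, pam_sets, max_mm)
  if (length(fwd$start)) {
    start0 <- fwd$start - 1L
    rows[[1]] <- tibble::tibble(
      guide = guide$name, chrom = chrom,
      start = start0, end = start0 + L, strand = "+",
      pam_start = start0 + L, pam_end = start0 + L + P,
      site_sequence = substring(seq_fwd, fwd$start, fwd$start + L - 1L),
      n_mismatches = fwd$n_mm, mismatch_offsets = fwd$offsets,
      bulge_type = "none", bulge_size = 0L, bulge_offset = NA_integer_,
      cut_site = start0 + L - 3L
    )
  }

  seq_rc <- revcomp(seq_fwd)
  code_rc <- encode_seq(seq_rc)
  rev_hit <- scan_strand_mismatch(code_rc, spacer_code, pam_sets, max_mm)
  if (length(rev_hit$start)) {
    a <- rev_hit$start  # 1-based start in rc coordinates
    start0 <- n - (a - 1L) - L
    rows[[2]] <- tibble::tibble(
      guide = guide$name, chrom = chrom,
      start = start0, end = start0 + L, strand = "-",
      pam_start = start0 - P, pam_end = start0,
      site_sequence = substring(seq_rc, a, a + L - 1L),
      n_mismatches = rev_hit$n_mm, mismatch_offsets = rev_hit$offsets,
      bulge_type = "none", bulge_size = 0L, bulge_offset = NA_integer_,
      cut_site = start0 + 3L
    )
  }
  dplyr::bind_rows(rows)
}

# ---- single-bulge gapped scan ---------------------------------------------

# Enumerate alignment configurations: for spacer offset k (distance from
# PAM, 1..L), the strand-local genomic index relative to the PAM start q is
# q - shift[k]; skipped spacer offsets (RNA bulge) carry shift NA.
bulge_configs <- function(L, max_bulge) {
  cfgs <- list(list(type = "none", b = 0L, o = NA_integer_,
                    shift = seq_len(L), span = L, rank = 0L))
  for (b in seq_len(max_bulge)) {
    for (o in seq_len(L - 1L)) {  # insertion after the o-th PAM-proximal base
      shift <- ifelse(seq_len(L) <= o, seq_len(L), seq_len(L) + b)
      cfgs[[length(cfgs) + 1L]] <-
        list(type = "dna", b = b, o = o, shift = as.integer(shift),
             span = L + b, rank = 1L)
    }
    if (L - b - 1L >= 1L) {
      for (o in seq_len(L - b - 1L)) {  # spacer offsets o+1..o+b skipped
        shift <- rep(NA_integer_, L)
        shift[seq_len(o)] <- seq_len(o)
        idx <- (o + b + 1L):L
        shift[idx] <- idx - b
        cfgs[[length(cfgs) + 1L]] <-
          list(type = "rna", b = b, o = o, shift = shift,
               span = L - b, rank = 2L)
      }
    }
  }
  cfgs
}

scan_strand_bulged <- function(code, spacer_code, pam_sets, max_mm, max_bulge) {
  L <- length(spacer_code)
  P <- length(pam_sets)
  n <- length(code)
  if (n < L + P) return(NULL)
  # PAM occurrence positions q (1-based PAM start), anywhere with room for
  # the PAM itself; flank room is checked per configuration.
  n_q <- n - P + 1L
  ok <- rep(TRUE, n_q)
  for (k in seq_len(P)) {
    ok <- ok & pam_sets[[k]][code[k:(k + n_q - 1L)] + 1L]
  }
  q_all <- which(ok)
  if (!length(q_all)) return(NULL)

  spacer_from_pam <- spacer_code[L:1L]  # index k = distance from PAM
  cfgs <- bulge_configs(L, max_bulge)

  nq <- length(q_all)
  best_b <- rep(Inf, nq); best_mm <- rep(Inf, nq)
  best_rank <- rep(Inf, nq); best_o <- rep(Inf, nq)
  best_cfg <- rep(NA_integer_, nq)
  best_mm_list <- vector("list", nq)

  for (ci in seq_along(cfgs)) {
    cfg <- cfgs[[ci]]
    need <- max(cfg$shift, na.rm = TRUE)
    usable <- which(q_all > need)
    if (!length(usable)) next
    q <- q_all[usable]
    mm_mat <- matrix(FALSE, length(q), L)
    for (k in seq_len(L)) {
      if (is.na(cfg$shift[k])) next
      mm_mat[, k] <- code[q - cfg$shift[k]] != spacer_from_pam[k]
    }
    n_mm <- as.integer(rowSums(mm_mat))
    cand <- which(n_mm <= max_mm)
    if (!length(cand)) next
    gi <- usable[cand]
    o_cmp <- if (is.na(cfg$o)) 0L else cfg$o
    better <- (cfg$b < best_b[gi]) |
      (cfg$b == best_b[gi] & n_mm[cand] < best_mm[gi]) |
      (cfg$b == best_b[gi] & n_mm[cand] == best_mm[gi] & cfg$rank < best_rank[gi]) |
      (cfg$b == best_b[gi] & n_mm[cand] == best_mm[gi] & cfg$rank == best_rank[gi] &
         o_cmp < best_o[gi])
    upd <- gi[better]
    if (!length(upd)) next
    sel <- cand[better]
    best_b[upd] <- cfg$b; best_mm[upd] <- n_mm[sel]
    best_rank[upd] <- cfg$rank; best_o[upd] <- o_cmp
    best_cfg[upd] <- ci
    for (t in seq_along(upd)) {
      best_mm_list[[upd[t]]] <- sort(which(mm_mat[sel[t], ]))
    }
  }

  hit <- which(!is.na(best_cfg))
  if (!length(hit)) return(NULL)
  list(
    q = q_all[hit],
    cfg = cfgs[best_cfg[hit]],
    n_mm = as.integer(best_mm[hit]),
    offsets = best_mm_list[hit]
  )
}

scan_contig_bulged <- function(chrom, seq_fwd, guide, pam_sets, max_mm, max_bulge) {
  L <- nchar(guide$spacer)
  P <- nchar(guide$pam)
  spacer_code <- encode_seq(guide$spacer)
  n <- nchar(seq_fwd)
  rows <- list()

  build <- function(hits, strand, seq_local) {
    if (is.null(hits)) return(NULL)
    span <- vapply(hits$cfg, `[[`, integer(1), "span")
    btype <- vapply(hits$cfg, `[[`, character(1), "type")
    bsize <- vapply(hits$cfg, `[[`, integer(1), "b")
    boff <- vapply(hits$cfg, function(c) c$o %||% NA_integer_, integer(1))
    q <- hits$q
    local_start0 <- q - 1L - span    # 0-based protospacer start, strand-local
    site_seq <- substring(seq_local, local_start0 + 1L, q - 1L)
    if (strand == "+") {
      start0 <- local_start0
      end0 <- q - 1L
      tibble::tibble(
        guide = guide$name, chrom = chrom, start = start0, end = end0,
        strand = "+", pam_start = end0, pam_end = end0 + P,
        site_sequence = site_seq, n_mismatches = hits$n_mm,
        mismatch_offsets = hits$offsets, bulge_type = btype,
        bulge_size = bsize, bulge_offset = boff, cut_site = end0 - 3L
      )
    } else {
      # map strand-local [local_start0, q-1) to genome coordinates
      start0 <- n - (q - 1L)
      end0 <- n - local_start0
      tibble::tibble(
        guide = guide$name, chrom = chrom, start = start0, end = end0,
        strand = "-", pam_start = start0 - P, pam_end = start0,
        site_sequence = site_seq, n_mismatches = hits$n_mm,
        mismatch_offsets = hits$offsets, bulge_type = btype,
        bulge_size = bsize, bulge_offset = boff, cut_site = start0 + 3L
      )
    }
  }

  code_fwd <- encode_seq(seq_fwd)
  rows[[1]] <- build(
    scan_strand_bulged(code_fwd, spacer_code, pam_sets, max_mm, max_bulge),
    "+", seq_fwd)
  seq_rc <- revcomp(seq_fwd)
  rows[[2]] <- build(
    scan_strand_bulged(encode_seq(seq_rc), spacer_code, pam_sets, max_mm, max_bulge),
    "-", seq_rc)
  dplyr::bind_rows(rows)
}

#' Predicted blunt cut coordinate of a matched site
#'
#' SpCas9 cleaves bluntly 3 bp PAM-proximal of the PAM (between protospacer
#' positions 17 and 18 of a 20-nt spacer). For a site on the plus strand with
#' the PAM at `[pam_start, pam_end)` the cut coordinate is `pam_start - 3`;
#' on the minus strand it is `pam_end + 3`. Pure function of the PAM
#' interval and strand; works for bulged sites too (the cut is anchored to
#' the PAM, not the protospacer length).
#'
#' @param sites A `caskas_sites` tibble (or any tibble with `pam_start`,
#'   `pam_end`, `strand`, `start`, `end` columns).
#' @return Integer vector of cut coordinates, one per site.
#' @export
predicted_cut_site <- function(sites) {
  if ((nrow(sites) > 0) && any(sites$end - sites$start < 4L)) {
    abort("cut position undefined for protospacers shorter than 4 nt")
  }
  ifelse(sites$strand == "+",
         as.integer(sites$pam_start - 3L),
         as.integer(sites$pam_end + 3L))
}

#' Write a site list as BED6
#'
#' Name field is `guide:n_mismatches:bulge` (bulge descriptor
#' `none`/`dna<size>@<offset>`/`rna<size>@<offset>`), score is
#' `20 - n_mismatches` floored at 0.
#'
#' @param sites A `caskas_sites` tibble.
#' @param path Output path.
#' @export
write_sites_bed <- function(sites, path) {
  bulge_desc <- ifelse(
    sites$bulge_type == "none", "none",
    paste0(sites$bulge_type, sites$bulge_size, "@", sites$bulge_offset))
  bed <- tibble::tibble(
    chrom = sites$chrom, start = sites$start, end = sites$end,
    name = paste(sites$guide, sites$n_mismatches, bulge_desc, sep = ":"),
    score = pmax(0L, 20L - sites$n_mismatches),
    strand = sites$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Per-position mismatch summary across ranked sites
#'
#' Builds a sites-by-position indicator matrix of mismatches indexed by
#' distance from the PAM, plus aggregate mismatch rates for the PAM-proximal
#' seed half (offsets 1..floor(L/2)) and the PAM-distal half. Sites are
#' ordered by decreasing weight (e.g. occupancy), mirroring ranked-site
#' specificity summaries.
#'
#' @param guide A [guide_rna()].
#' @param sites A `caskas_sites` tibble.
#' @param weights Optional numeric weights (one per site) used for ordering;
#'   defaults to the sites' `rpm_ot` column if present, else equal weights.
#' @return Object of class `mismatch_matrix`: list with `guide`, `matrix`
#'   (rows = sites in weight order), `weights`, `frequency` (per offset),
#'   `seed_rate`, `distal_rate`.
#' @export
mismatch_position_matrix <- function(guide, sites, weights = NULL) {
  L <- nchar(guide$spacer)
  n <- nrow(sites)
  if (is.null(weights)) {
    weights <- if ("rpm_ot" %in% names(sites)) sites$rpm_ot else rep(1, n)
  }
  stopifnot(length(weights) == n)
  ord <- order(weights, decreasing = TRUE)
  mat <- matrix(0, nrow = n, ncol = L,
                dimnames = list(NULL, paste0("offset_", seq_len(L))))
  if (n > 0) {
    offs <- sites$mismatch_offsets[ord]
    for (i in seq_len(n)) {
      if (length(offs[[i]])) mat[i, offs[[i]]] <- 1
    }
  }
  seed_idx <- seq_len(floor(L / 2))
  distal_idx <- setdiff(seq_len(L), seed_idx)
  freq <- if (n > 0) colMeans(mat) else setNames(numeric(L), colnames(mat))
  structure(list(
    guide = guide, matrix = mat, weights = weights[ord],
    frequency = freq,
    seed_rate = if (n > 0) mean(mat[, seed_idx]) else NaN,
    distal_rate = if (n > 0) mean(mat[, distal_idx]) else NaN
  ), class = "mismatch_matrix")
}

#' @export
print.mismatch_matrix <- function(x, ...) {
  cat(sprintf("<mismatch_matrix> %s: %d sites x %d positions; seed rate %.3f, distal rate %.3f\n",
              x$guide$name, nrow(x$matrix), ncol(x$matrix),
              x$seed_rate, x$distal_rate))
  invisible(x)
}

#' Export a mismatch matrix as TSV
#' @param x A `mismatch_matrix`.
#' @param path Output path.
#' @export
write_mismatch_matrix <- function(x, path) {
  df <- tibble::as_tibble(x$matrix)
  df <- dplyr::mutate(df, weight = x$weights, .before = 1)
  readr::write_tsv(df, path)
  invisible(path)
}
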