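# Independent oracles used to cross-check the package implementation.
# These deliberately use different mechanics (window matrices, string
# surgery, double loops) than the vectorized implementations they verify.

IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

random_genome <- function(len, seed, gc = 0.5, name = "chr1") {
  withr::with_seed(seed, {
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    setNames(paste(sample(c("A", "C", "G", "T"), len, TRUE, p), collapse = ""),
             name)
  })
}

# All-windows mismatch oracle: builds an explicit windows-by-position
# character matrix per strand and compares column-wise.
oracle_scan_strand <- function(seq, spacer, pam, max_mm) {
  chars <- strsplit(seq, "")[[1]]
  sp <- strsplit(spacer, "")[[1]]
  pm <- strsplit(pam, "")[[1]]
  L <- length(sp); P <- length(pm); n <- length(chars)
  if (n < L + P) return(NULL)
  starts <- seq_len(n - L - P + 1L)
  pam_ok <- rep(TRUE, length(starts))
  for (j in seq_len(P)) {
    pam_ok <- pam_ok & chars[starts + L + j - 1L] %in% IUPAC[[pm[j]]]
  }
  starts <- starts[pam_ok]
  if (!length(starts)) return(NULL)
  M <- matrix(chars[outer(starts, 0:(L - 1L), "+")], nrow = length(starts))
  mism <- M != matrix(sp, nrow = length(starts), ncol = L, byrow = TRUE)
  n_mm <- rowSums(mism)
  keep <- n_mm <= max_mm
  if (!any(keep)) return(NULL)
  list(start1 = starts[keep], n_mm = as.integer(n_mm[keep]),
       offsets = lapply(which(keep), function(i) {
         sort(L - which(mism[i, ]) + 1L)
       }))
}

oracle_find_sites <- function(genome, guide, max_mm) {
  L <- nchar(guide$spacer)
  out <- list()
  for (chrom in names(genome)) {
    seq <- toupper(genome[[chrom]])
    n <- nchar(seq)
    f <- oracle_scan_strand(seq, guide$spacer, guide$pam, max_mm)
    if (!is.null(f)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        chrom = chrom, start = f$start1 - 1L, end = f$start1 - 1L + L,
        strand = "+", n_mismatches = f$n_mm, mismatch_offsets = f$offsets)
    }
    r <- oracle_scan_strand(oracle_revcomp(seq), guide$spacer, guide$pam, max_mm)
    if (!is.null(r)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        chrom = chrom, start = n - (r$start1 - 1L) - L,
        end = n - (r$start1 - 1L), strand = "-",
        n_mismatches = r$n_mm, mismatch_offsets = r$offsets)
    }
  }
  empty <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), strand = character(),
                          n_mismatches = integer(), mismatch_offsets = list())
  df <- dplyr::bind_rows(c(list(empty), out))
  dplyr::arrange(df, chrom, start, strand)
}

# String-surgery oracle for the single-bulge search: explicitly deletes
# inserted genomic bases / skipped spacer bases and compares the resulting
# strings, picking the best alignment per PAM locus under the documented
# tie-break (bulged bases, mismatches, DNA before RNA, bulge nearest PAM).
oracle_scan_strand_bulged <- function(seq, spacer, pam, max_mm, max_b) {
  chars <- strsplit(seq, "")[[1]]
  sp_pam <- rev(strsplit(spacer, "")[[1]])  # index = distance from PAM
  pm <- strsplit(pam, "")[[1]]
  L <- length(sp_pam); P <- length(pm); n <- length(chars)
  qs <- seq_len(n - P + 1L)
  for (j in seq_len(P)) qs <- qs[chars[qs + j - 1L] %in% IUPAC[[pm[j]]]]
  res <- list()
  for (q in qs) {
    cand <- list()
    flank_max <- q - 1L
    gp <- if (flank_max > 0) chars[(q - 1L):max(1L, q - L - max_b)] else character()
    # gp[k] = base at distance k PAM-proximal of the PAM
    if (length(gp) >= L) {
      mm <- sum(gp[seq_len(L)] != sp_pam)
      if (mm <= max_mm) cand[[length(cand) + 1L]] <-
          list(b = 0L, mm = mm, rank = 0L, o = 0L, type = "none", span = L)
    }
    for (b in seq_len(max_b)) {
      if (length(gp) >= L + b) {
        for (o in seq_len(L - 1L)) {
          g2 <- gp[-((o + 1L):(o + b))]
          mm <- sum(g2[seq_len(L)] != sp_pam)
          if (mm <= max_mm) cand[[length(cand) + 1L]] <-
              list(b = b, mm = mm, rank = 1L, o = o, type = "dna", span = L + b)
        }
      }
      if (length(gp) >= L - b && L - b - 1L >= 1L) {
        for (o in seq_len(L - b - 1L)) {
          s2 <- sp_pam[-((o + 1L):(o + b))]
          mm <- sum(gp[seq_len(L - b)] != s2)
          if (mm <= max_mm) cand[[length(cand) + 1L]] <-
              list(b = b, mm = mm, rank = 2L, o = o, type = "rna", span = L - b)
        }
      }
    }
    if (!length(cand)) next
    keys <- t(vapply(cand, function(x) c(x$b, x$mm, x$rank, x$o), numeric(4)))
    best <- cand[[order(keys[, 1], keys[, 2], keys[, 3], keys[, 4])[1]]]
    res[[length(res) + 1L]] <- tibble::tibble(
      q = q, b = best$b, mm = best$mm, type = best$type,
      o = ifelse(best$type == "none", NA_integer_, best$o), span = best$span)
  }
  dplyr::bind_rows(res)
}

oracle_find_sites_bulged <- function(genome, guide, max_mm, max_b) {
  out <- list()
  for (chrom in names(genome)) {
    seq <- toupper(genome[[chrom]])
    n <- nchar(seq)
    f <- oracle_scan_strand_bulged(seq, guide$spacer, guide$pam, max_mm, max_b)
    if (nrow(f)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        chrom = chrom, start = f$q - 1L - f$span, end = f$q - 1L,
        strand = "+", n_mismatches = f$mm, bulge_type = f$type,
        bulge_size = f$b, bulge_offset = f$o)
    }
    r <- oracle_scan_strand_bulged(oracle_revcomp(seq), guide$spacer,
                                   guide$pam, max_mm, max_b)
    if (nrow(r)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        chrom = chrom, start = n - (r$q - 1L), end = n - (r$q - 1L - r$span),
        strand = "-", n_mismatches = r$mm, bulge_type = r$type,
        bulge_size = r$b, bulge_offset = r$o)
    }
  }
  empty <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), strand = character(),
                          n_mismatches = integer(), bulge_type = character(),
                          bulge_size = integer(), bulge_offset = integer())
  df <- dplyr::bind_rows(c(list(empty), out))
  dplyr::arrange(df, chrom, start, strand)
}

# Brute-force per-site overlap counter for the RPM oracle.
oracle_rpm_ot <- function(reads, sites, flank = 500L) {
  mates <- crisprkas:::expand_to_reads(reads)
  vapply(seq_len(nrow(sites)), function(i) {
    ws <- max(0L, sites$cut_site[i] - flank)
    we <- min(reads$contigs[[sites$chrom[i]]], sites$cut_site[i] + flank + 1L)
    m <- mates[mates$chrom == sites$chrom[i], ]
    sum(m$start < we & m$end > ws) * 1e6 / reads$library_size
  }, numeric(1))
}

# Naive double-loop evaluation of the 3-bp-window product score.
oracle_c_score <- function(plus, minus) {
  n <- length(plus)
  vapply(seq_len(n), function(i) {
    idx <- max(1L, i - 1L):min(n, i + 1L)
    sum(plus[idx]) * sum(minus[idx])
  }, numeric(1))
}

# Deterministic cassette construction for planting test sites directly in
# a sequence string (no reliance on the package's own generator).
mutate_spacer_offsets <- function(spacer, offsets) {
  from_pam <- rev(strsplit(spacer, "")[[1]])
  rot <- c(A = "C", C = "G", G = "T", T = "A")
  for (o in offsets) from_pam[o] <- rot[[from_pam[o]]]
  paste(rev(from_pam), collapse = "")
}

insert_at_offset <- function(spacer, offset, base) {
  from_pam <- rev(strsplit(spacer, "")[[1]])
  paste(rev(append(from_pam, base, after = offset)), collapse = "")
}

delete_at_offsets <- function(spacer, offsets) {
  from_pam <- rev(strsplit(spacer, "")[[1]])
  paste(rev(from_pam[-offsets]), collapse = "")
}

splice_cassette <- function(seq, cassette, at, strand = "+") {
  if (strand == "-") cassette <- oracle_revcomp(cassette)
  paste0(substr(seq, 1, at), cassette,
         substr(seq, at + nchar(cassette) + 1, nchar(seq)))
}

site_key <- function(df) {
  paste(df$chrom, df$start, df$end, df$strand, df$n_mismatches, sep = "|")
}

# Small simulated dCas9 dataset reused across tests.
make_small_sim <- function(seed, n_sites = 3, genome_len = 50000,
                           n_fragments = 20000, background_rate = 0.3,
                           nuclease = "dcas9", cut_fraction = 0,
                           occupancy = NULL, ...) {
  g <- guide_rna("sg1", "GCTTAATTAAGGTAAACGTC")
  planted <- tibble::tibble(
    guide = "sg1",
    n_mismatches = rep(0L, n_sites),
    strand = rep_len(c("+", "-"), n_sites),
    occupancy = if (is.null(occupancy)) rep(1, n_sites) else occupancy,
    cut_fraction = rep(cut_fraction, n_sites))
  sim <- make_genome(genome_len, 0.45, seed = seed, guides = g,
                     planted = planted)
  cfg <- sim_config(sim, n_fragments = n_fragments,
                    background_rate = background_rate, nuclease = nuclease,
                    ...)
  list(sim = sim, cfg = cfg, guide = g)
}
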