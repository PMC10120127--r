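# Fragment simulator: guanine-dependent labeling of R-loop bubbles,
# ChIP-like asymmetric capture, phased cleavage ends, uniform and
# "transcribed-interval" backgrounds, duplicates, and matched no-guide
# controls. All randomness flows through per-component streams derived from
# one master seed, so the background draws do not depend on how many sites
# are planted.

#' Configure a simulated sequencing experiment
#'
#' @param sim A `sim_genome` from [make_genome()].
#' @param n_fragments Total fragment attempts (site attempts + background).
#' @param background_rate Fraction of attempts drawn from the background
#'   model rather than from planted sites.
#' @param nuclease `"dcas9"` (binding only) or `"cas9"` (binding +
#'   cleavage via per-site `cut_fraction`).
#' @param mode `"in_vitro"` (uniform background) or `"in_vivo"` (uniform
#'   background plus elevated two-strand signal over `active_intervals`,
#'   emulating endogenous ssDNA over transcribed regions).
#' @param fragment_length Length bounds of sonicated fragments, default
#'   `c(150, 400)` (uniform over the range).
#' @param labeling_per_G Per-exposed-guanine probability that kethoxal
#'   labeling captures the molecule (default 0.5).
#' @param active_intervals Tibble (`chrom`, `start`, `end`) of intervals
#'   with elevated background; required for `mode = "in_vivo"`.
#' @param active_fold Fold elevation of per-base background rate inside
#'   active intervals (default 5).
#' @param duplicate_rate Probability that an emitted fragment is resampled
#'   as a PCR-style exact duplicate (default 0).
#' @param read_length Mate read length used when expanding fragments to
#'   reads (default 36, as in 2x36 nt sequencing).
#' @param cut_offsets Non-target-strand cut positions, in bp from the PAM
#'   (default `c(3, 4, 5)`); the target strand is always cut bluntly at
#'   3 bp.
#' @param cut_weights Sampling weights of `cut_offsets`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(sim, n_fragments, background_rate = 0.5,
                       nuclease = c("dcas9", "cas9"),
                       mode = c("in_vitro", "in_vivo"),
                       fragment_length = c(150L, 400L),
                       labeling_per_G = 0.5,
                       active_intervals = NULL, active_fold = 5,
                       duplicate_rate = 0, read_length = 36L,
                       cut_offsets = c(3L, 4L, 5L),
                       cut_weights = c(0.5, 0.3, 0.2)) {
  nuclease <- match.arg(nuclease)
  mode <- match.arg(mode)
  stopifnot(inherits(sim, "sim_genome"), n_fragments > 0,
            background_rate >= 0, background_rate <= 1,
            labeling_per_G >= 0, labeling_per_G <= 1,
            duplicate_rate >= 0, duplicate_rate <= 1,
            length(fragment_length) == 2L,
            length(cut_offsets) == length(cut_weights))
  if (fragment_length[1] < 20 || fragment_length[2] > min(sim$contigs) ||
      fragment_length[1] > fragment_length[2]) {
    abort("fragment_length bounds must lie within [20, genome length]")
  }
  if (mode == "in_vivo") {
    if (is.null(active_intervals) || nrow(active_intervals) == 0) {
      abort("in_vivo mode requires active_intervals")
    }
    check_contigs(active_intervals, sim$contigs)
  }
  structure(list(
    sim = sim, n_fragments = as.integer(n_fragments),
    background_rate = background_rate, nuclease = nuclease, mode = mode,
    fragment_length = as.integer(fragment_length),
    labeling_per_G = labeling_per_G,
    active_intervals = active_intervals, active_fold = active_fold,
    duplicate_rate = duplicate_rate, read_length = as.integer(read_length),
    cut_offsets = as.integer(cut_offsets),
    cut_weights = cut_weights / sum(cut_weights)
  ), class = "sim_config")
}

# Exposed-G positions (0-based genome coordinates) of a site's R-loop
# bubble: the displaced non-target strand carries the protospacer sequence,
# so on a plus-strand site the exposed Gs are plus-strand Gs within the
# protospacer; on a minus-strand site they are plus-strand Cs.
exposed_g_positions <- function(sim, site) {
  seq_chr <- sim$genome[[site$chrom]]
  window <- substring(seq_chr, site$start + 1L, site$end)
  chars <- strsplit(window, "")[[1]]
  want <- if (site$strand == "+") "G" else "C"
  site$start + which(chars == want) - 1L
}

largest_remainder_alloc <- function(total, weights) {
  if (total == 0 || sum(weights) == 0) return(rep(0L, length(weights)))
  exact <- total * weights / sum(weights)
  base <- floor(exact)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Simulate CasKAS-style fragments
#'
#' Draws site-derived fragments (labeling model: a molecule is captured if a
#' per-exposed-G Bernoulli succeeds for at least one bubble guanine; the
#' sonicated fragment is a uniform-breakpoint interval constrained to
#' overlap the labeled base), applies cleavage truncation for active Cas9,
#' adds background (uniform, plus elevated active-interval signal in vivo)
#' and optional duplicates.
#'
#' Stream discipline: site `k` uses a seed derived from `(seed, 100 + k)`,
#' the background uses `(seed, 1)` and duplicates `(seed, 2)`, so adding or
#' removing a planted site never perturbs the background draws. Within a
#' site stream the draw order is: capture indicators, labeled-G choices,
#' fragment lengths, breakpoint offsets, cleavage indicators, stagger
#' offsets.
#'
#' @param config A [sim_config()].
#' @param seed Integer master seed.
#' @param control If `TRUE`, simulate the matched no-guide control: the same
#'   generative process with every site occupancy set to 0.
#' @return Tibble of fragments: `chrom`, `start`, `end` (0-based half-open),
#'   `origin` in `site_binding`, `site_cleaved_left`, `site_cleaved_right`,
#'   `background`, `active_region`.
#' @export
simulate_fragments <- function(config, seed, control = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  sim <- config$sim
  sites <- sim$sites
  lo <- config$fragment_length[1]
  hi <- config$fragment_length[2]
  min_piece <- 20L
  out <- list()

  n_site_total <- round(config$n_fragments * (1 - config$background_rate))
  occ <- if (control || nrow(sites) == 0) rep(0, nrow(sites)) else sites$occupancy
  if (n_site_total > 0 && sum(occ) > 0) {
    alloc <- largest_remainder_alloc(n_site_total, occ)
    for (k in seq_len(nrow(sites))) {
      if (alloc[k] == 0) next
      site <- sites[k, ]
      g_pos <- exposed_g_positions(sim, site)
      if (length(g_pos) == 0) next  # zero exposed Gs: invisible to labeling
      clen <- sim$contigs[[site$chrom]]
      frag <- withr::with_seed(derive_seed(seed, 100 + k), {
        p_succ <- 1 - (1 - config$labeling_per_G)^length(g_pos)
        captured <- rbinom(alloc[k], 1L, p_succ) == 1L
        n_cap <- sum(captured)
        res <- NULL
        if (n_cap > 0) {
        g <- if (length(g_pos) == 1L) rep(g_pos, n_cap) else
          sample(g_pos, n_cap, replace = TRUE)
        len <- if (lo == hi) rep(lo, n_cap) else
          sample(seq(lo, hi), n_cap, replace = TRUE)
        off <- floor(runif(n_cap) * len)
        start <- pmax(0L, g - off)
        end <- pmin(clen, start + len)
        res <- tibble::tibble(chrom = site$chrom,
                              start = as.integer(start),
                              end = as.integer(end),
                              origin = "site_binding")
        if (config$nuclease == "cas9" && site$cut_fraction > 0) {
          cleaved <- rbinom(n_cap, 1L, site$cut_fraction) == 1L
          if (any(cleaved)) {
            delta <- sample(config$cut_offsets, sum(cleaved), replace = TRUE,
                            prob = config$cut_weights)
            if (site$strand == "+") {
              left_end <- rep(site$pam_start - 3L, sum(cleaved))
              right_start <- site$pam_start - delta
            } else {
              left_end <- site$pam_end + delta
              right_start <- rep(site$pam_end + 3L, sum(cleaved))
            }
            cs <- res$start[cleaved]; ce <- res$end[cleaved]
            left <- tibble::tibble(
              chrom = site$chrom, start = cs,
              end = pmin(ce, as.integer(left_end)),
              origin = "site_cleaved_left")
            right <- tibble::tibble(
              chrom = site$chrom, start = pmax(cs, as.integer(right_start)),
              end = ce, origin = "site_cleaved_right")
            pieces <- dplyr::bind_rows(left, right)
            pieces <- pieces[pieces$end - pieces$start >= min_piece, ]
            res <- dplyr::bind_rows(res[!cleaved, ], pieces)
          }
        }
        }
        res
      })
      out[[length(out) + 1L]] <- frag
    }
  }

  n_bg <- config$n_fragments - n_site_total
  if (n_bg > 0) {
    bg <- withr::with_seed(derive_seed(seed, 1), {
      chrom_pick <- if (length(sim$contigs) == 1L) {
        rep(names(sim$contigs), n_bg)
      } else {
        sample(names(sim$contigs), n_bg, replace = TRUE,
               prob = sim$contigs / sum(sim$contigs))
      }
      len <- if (lo == hi) rep(lo, n_bg) else
        sample(seq(lo, hi), n_bg, replace = TRUE)
      clen <- unname(sim$contigs[chrom_pick])
      origin <- rep("background", n_bg)
      start <- integer(n_bg)
      if (config$mode == "in_vivo") {
        act <- config$active_intervals
        act_len <- sum(act$end - act$start)
        # uniform component spans the whole genome, so the extra active
        # weight is (fold - 1) x to make the total rate inside = fold x
        w_active <- (config$active_fold - 1) * act_len
        p_active <- w_active / (w_active + sum(sim$contigs))
        is_active <- runif(n_bg) < p_active
        origin[is_active] <- "active_region"
        # active fragments: midpoint uniform over the concatenated intervals
        n_act <- sum(is_active)
        if (n_act > 0) {
          widths <- act$end - act$start
          iv <- sample(seq_len(nrow(act)), n_act, replace = TRUE, prob = widths)
          mid <- act$start[iv] + floor(runif(n_act) * widths[iv])
          chrom_pick[is_active] <- act$chrom[iv]
          clen[is_active] <- unname(sim$contigs[act$chrom[iv]])
          start[is_active] <- mid - len[is_active] %/% 2L
        }
        n_uni <- sum(!is_active)
        if (n_uni > 0) {
          start[!is_active] <-
            floor(runif(n_uni) * (clen[!is_active] - len[!is_active] + 1))
        }
      } else {
        start <- floor(runif(n_bg) * (clen - len + 1))
      }
      start <- pmax(0L, as.integer(start))
      end <- pmin(clen, start + len)
      tibble::tibble(chrom = chrom_pick, start = as.integer(start),
                     end = as.integer(end), origin = origin)
    })
    out[[length(out) + 1L]] <- bg
  }

  frags <- dplyr::bind_rows(out)
  if (nrow(frags) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), origin = character()))
  }
  if (config$duplicate_rate > 0) {
    dups <- withr::with_seed(derive_seed(seed, 2), {
      n_dup <- rbinom(1L, nrow(frags), config$duplicate_rate)
      if (n_dup == 0) NULL else frags[sample.int(nrow(frags), n_dup, replace = TRUE), ]
    })
    frags <- dplyr::bind_rows(frags, dups)
  }
  frags
}

#' Simulate a treatment experiment with its matched no-guide control
#'
#' @inheritParams simulate_fragments
#' @param with_control Simulate the no-guide control (default `TRUE` for
#'   `in_vivo` mode). The control is the same generative process with all
#'   occupancies set to 0, under the same stream discipline with a derived
#'   seed.
#' @return Object of class `sim_result`: list with `treatment`, `control`
#'   (or `NULL`), `config`, `seed`.
#' @export
simulate_experiment <- function(config, seed,
                                with_control = config$mode == "in_vivo") {
  treatment <- simulate_fragments(config, seed)
  control <- if (with_control) {
    simulate_fragments(config, derive_seed(seed, 7), control = TRUE)
  }
  structure(list(treatment = treatment, control = control,
                 config = config, seed = seed),
            class = "sim_result")
}

# ---- serialization ---------------------------------------------------------

fragments_to_reads <- function(frags, read_length) {
  rl <- pmin(read_length, frags$end - frags$start)
  dplyr::bind_rows(
    tibble::tibble(chrom = frags$chrom, start = frags$start,
                   end = frags$start + rl, strand = "+",
                   frag = seq_len(nrow(frags))),
    tibble::tibble(chrom = frags$chrom, start = frags$end - rl,
                   end = frags$end, strand = "-",
                   frag = seq_len(nrow(frags)))
  )
}

write_fragments_bed <- function(frags, path) {
  bed <- tibble::tibble(chrom = frags$chrom, start = frags$start,
                        end = frags$end, name = frags$origin,
                        score = 0L, strand = ".")
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

write_reads_bed <- function(frags, path, read_length) {
  reads <- fragments_to_reads(frags, read_length)
  bed <- tibble::tibble(chrom = reads$chrom, start = reads$start,
                        end = reads$end,
                        name = paste0("frag", reads$frag),
                        score = 0L, strand = reads$strand)
  bed <- bed[order(reads$frag, reads$strand), ]
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

write_fragments_sam <- function(frags, genome, path, read_length) {
  contigs <- contig_lengths(genome)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), as.integer(contigs)))
  rl <- pmin(read_length, frags$end - frags$start)
  tlen <- frags$end - frags$start
  pos1 <- frags$start + 1L
  pos2 <- frags$end - rl + 1L
  seq1 <- substring(genome[frags$chrom], pos1, pos1 + rl - 1L)
  seq2 <- substring(genome[frags$chrom], pos2, pos2 + rl - 1L)
  seq2 <- vapply(seq2, revcomp, character(1), USE.NAMES = FALSE)
  qual <- strrep("I", rl)
  qname <- sprintf("frag%06d", seq_len(nrow(frags)))
  cigar <- sprintf("%dM", rl)
  l1 <- paste(qname, 99L, frags$chrom, pos1, 60L, cigar, "=", pos2, tlen,
              seq1, qual, sep = "\t")
  l2 <- paste(qname, 147L, frags$chrom, pos2, 60L, cigar, "=", pos1, -tlen,
              seq2, qual, sep = "\t")
  lines <- c(header, as.vector(rbind(l1, l2)))
  writeLines(lines, path)
  invisible(path)
}

#' Write a simulated experiment to disk
#'
#' Emits the reference FASTA, fragment and read BED6 files, an optional
#' paired-end SAM, the ground-truth planted-site table, and a resolved
#' config manifest. Output is byte-identical across runs on the same
#' objects.
#'
#' @param result A `sim_result` from [simulate_experiment()].
#' @param dir Output directory (created if missing).
#' @param write_sam Also emit SAM alignments (default `TRUE`).
#' @return Named character vector of written paths, invisibly.
#' @export
write_simulation <- function(result, dir, write_sam = TRUE) {
  stopifnot(inherits(result, "sim_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- result$config$sim
  paths <- c(genome = file.path(dir, "genome.fa"))
  write_genome_fasta(sim$genome, paths["genome"])

  paths["fragments"] <- file.path(dir, "fragments_treatment.bed")
  write_fragments_bed(result$treatment, paths["fragments"])
  paths["reads"] <- file.path(dir, "reads_treatment.bed")
  write_reads_bed(result$treatment, paths["reads"], result$config$read_length)
  if (write_sam) {
    paths["sam"] <- file.path(dir, "treatment.sam")
    write_fragments_sam(result$treatment, sim$genome, paths["sam"],
                        result$config$read_length)
  }
  if (!is.null(result$control)) {
    paths["fragments_control"] <- file.path(dir, "fragments_control.bed")
    write_fragments_bed(result$control, paths["fragments_control"])
  }

  paths["truth"] <- file.path(dir, "truth_sites.tsv")
  truth <- dplyr::select(sim$sites, -"mismatch_offsets")
  readr::write_tsv(truth, paths["truth"])

  paths["manifest"] <- file.path(dir, "manifest.yaml")
  cfg <- result$config
  manifest <- list(
    package = "crisprkas",
    seed = result$seed,
    n_fragments = cfg$n_fragments, background_rate = cfg$background_rate,
    nuclease = cfg$nuclease, mode = cfg$mode,
    fragment_length = cfg$fragment_length,
    labeling_per_G = cfg$labeling_per_G,
    duplicate_rate = cfg$duplicate_rate, read_length = cfg$read_length,
    cut_offsets = cfg$cut_offsets, cut_weights = cfg$cut_weights,
    genome_seed = sim$seed, gc_content = sim$gc_content,
    contigs = as.list(sim$contigs)
  )
  writeLines(yaml::as.yaml(manifest), paths["manifest"])
  invisible(paths)
}
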