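# Reference genome I/O and synthetic genome construction with planted
# protospacer sites.

#' Read a multi-contig FASTA into a named character vector
#' @param path FASTA path.
#' @return Named character vector of uppercase contig sequences.
#' @export
read_genome_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(dss))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write a named character vector of contigs as FASTA
#' @param genome Named character vector.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  dss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(dss, path, width = 80L)
  invisible(path)
}

sample_bases <- function(n, gc_content) {
  p <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2,
         (1 - gc_content) / 2)
  sample(BASES, n, replace = TRUE, prob = p)
}

instantiate_pam <- function(pam) {
  chars <- strsplit(pam, "")[[1]]
  paste(vapply(chars, function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (length(set) == 1L) set else sample(set, 1L)
  }, character(1)), collapse = "")
}

# Build the plus-strand protospacer sequence of a planted site: apply the
# requested mismatches (offsets counted from the PAM) and at most one bulge.
build_site_sequence <- function(spacer, n_mismatches = 0L, mismatch_offsets = NULL,
                                bulge_type = "none", bulge_size = 0L,
                                bulge_offset = NA_integer_) {
  L <- nchar(spacer)
  from_pam <- rev(strsplit(spacer, "")[[1]])  # index = distance from PAM
  skipped <- integer()
  if (bulge_type == "rna") {
    skipped <- (bulge_offset + 1L):(bulge_offset + bulge_size)
  }
  if (is.null(mismatch_offsets)) {
    pool <- setdiff(seq_len(L), skipped)
    mismatch_offsets <- if (n_mismatches > 0) sort(sample(pool, n_mismatches)) else integer()
  }
  for (o in mismatch_offsets) {
    from_pam[o] <- sample(setdiff(BASES, from_pam[o]), 1L)
  }
  if (bulge_type == "rna") from_pam <- from_pam[-skipped]
  if (bulge_type == "dna") {
    ins <- vapply(seq_len(bulge_size), function(i) {
      sample(setdiff(BASES, from_pam[bulge_offset]), 1L)
    }, character(1))
    from_pam <- append(from_pam, ins, after = bulge_offset)
  }
  paste(rev(from_pam), collapse = "")
}

#' Build a seeded synthetic genome with planted guide target sites
#'
#' Generates an i.i.d. nucleotide background at the requested GC content and
#' plants protospacer + PAM cassettes for one or more guides, each with a
#' specified mismatch count (or explicit mismatch offsets), optional bulge,
#' strand, occupancy and cut fraction. After construction the genome is
#' re-scanned with [find_sites()] and every planted site must be recovered
#' at its stated (mismatch, bulge) budget, otherwise construction fails.
#' Fully deterministic for a fixed seed.
#'
#' @param length Contig length in bp (single contig named `sim1`), or a
#'   named vector of contig lengths.
#' @param gc_content GC fraction of the background (default 0.41,
#'   a mammalian-like value).
#' @param seed Integer seed; the genome is bit-for-bit reproducible.
#' @param guides A [guide_rna()] or named list of them.
#' @param planted Data frame describing sites to plant. Recognised columns
#'   (all optional except none): `guide` (name, default first guide),
#'   `strand` ("+"/"-", default "+"), `n_mismatches` (default 0),
#'   `mismatch_offsets` (list column of PAM-distance offsets),
#'   `bulge_type` ("none"/"dna"/"rna"), `bulge_size`, `bulge_offset`,
#'   `position` (0-based protospacer start on the plus strand; sampled if
#'   absent), `chrom`, `occupancy` (default 1), `cut_fraction` (default 0).
#'   `NULL` plants nothing.
#' @param margin Minimum distance between planted cassettes and from contig
#'   ends (default 1000 bp, leaving room for 150-400 bp fragments).
#' @return Object of class `sim_genome`: list with `genome` (named character
#'   vector), `contigs` (lengths), `guides`, and `sites` (a `caskas_sites`
#'   tibble augmented with `occupancy` and `cut_fraction`).
#' @export
make_genome <- function(length, gc_content = 0.41, seed = 1L, guides = NULL,
                        planted = NULL, margin = 1000L) {
  if (is.null(names(length))) {
    length <- setNames(as.integer(length), paste0("sim", seq_along(length)))
  }
  stopifnot(all(length > 0), gc_content > 0, gc_content < 1)
  if (inherits(guides, "guide_rna")) guides <- setNames(list(guides), guides$name)

  withr::with_seed(seed, {
    chars <- lapply(length, function(n) sample_bases(n, gc_content))

    sites_truth <- NULL
    if (!is.null(planted) && nrow(planted) > 0) {
      if (is.null(guides)) abort("planted sites require guides")
      planted <- tibble::as_tibble(planted)
      n <- nrow(planted)
      fill <- function(col, default) {
        if (col %in% names(planted)) planted[[col]] else rep(default, n)
      }
      spec <- tibble::tibble(
        guide = fill("guide", names(guides)[1]),
        chrom = fill("chrom", names(length)[1]),
        strand = fill("strand", "+"),
        n_mismatches = as.integer(fill("n_mismatches", 0L)),
        bulge_type = fill("bulge_type", "none"),
        bulge_size = as.integer(fill("bulge_size", 0L)),
        bulge_offset = as.integer(fill("bulge_offset", NA_integer_)),
        position = as.integer(fill("position", NA_integer_)),
        occupancy = as.numeric(fill("occupancy", 1)),
        cut_fraction = as.numeric(fill("cut_fraction", 0))
      )
      spec$mismatch_offsets <- if ("mismatch_offsets" %in% names(planted)) {
        planted$mismatch_offsets
      } else {
        rep(list(NULL), n)
      }
      if (any(!spec$guide %in% names(guides))) {
        abort("planted$guide refers to an unknown guide name")
      }
      if (any(spec$occupancy < 0) || any(spec$cut_fraction < 0 | spec$cut_fraction > 1)) {
        abort("occupancy must be >= 0 and cut_fraction in [0, 1]")
      }

      # construct cassettes, then place them without overlap
      cassettes <- lapply(seq_len(n), function(i) {
        g <- guides[[spec$guide[i]]]
        proto <- build_site_sequence(g$spacer, spec$n_mismatches[i],
                                     spec$mismatch_offsets[[i]],
                                     spec$bulge_type[i], spec$bulge_size[i],
                                     spec$bulge_offset[i])
        pam <- instantiate_pam(g$pam)
        cassette <- paste0(proto, pam)
        if (spec$strand[i] == "-") cassette <- revcomp(cassette)
        list(cassette = cassette, proto_len = nchar(proto),
             pam_len = nchar(pam))
      })

      occupied <- lapply(length, function(...) cbind(integer(), integer()))
      for (i in seq_len(n)) {
        cz <- nchar(cassettes[[i]]$cassette)
        chrom <- spec$chrom[i]
        clen <- length[[chrom]]
        if (clen < 2 * margin + cz) abort("contig too short for planted site with margin")
        place_start <- spec$position[i]
        if (!is.na(place_start)) {
          # position is the protospacer start; cassette start depends on strand
          cas_start <- if (spec$strand[i] == "+") place_start else
            place_start - cassettes[[i]]$pam_len
          if (overlaps_any(occupied[[chrom]], cas_start, cas_start + cz)) {
            abort(sprintf("planted site %d collides with an earlier site", i))
          }
        } else {
          cas_start <- NA
          for (try in 1:200) {
            cand <- sample.int(clen - 2L * margin - cz, 1L) + margin
            if (!overlaps_any(occupied[[chrom]], cand - margin, cand + cz + margin)) {
              cas_start <- cand
              break
            }
          }
          if (is.na(cas_start)) abort("could not place planted sites without collision")
        }
        occupied[[chrom]] <- rbind(occupied[[chrom]], c(cas_start, cas_start + cz))
        chars[[chrom]][(cas_start + 1L):(cas_start + cz)] <-
          strsplit(cassettes[[i]]$cassette, "")[[1]]
        proto_start <- if (spec$strand[i] == "+") cas_start else
          cas_start + cassettes[[i]]$pam_len
        spec$position[i] <- proto_start
      }
      sites_truth <- spec
    }

    genome <- vapply(chars, paste, character(1), collapse = "")
  })

  sites <- empty_sites()
  sites$occupancy <- numeric()
  sites$cut_fraction <- numeric()
  if (!is.null(sites_truth)) {
    found <- dplyr::bind_rows(lapply(unique(sites_truth$guide), function(gn) {
      budget_mm <- max(sites_truth$n_mismatches[sites_truth$guide == gn])
      budget_b <- max(sites_truth$bulge_size[sites_truth$guide == gn])
      find_sites(genome, guides[[gn]], budget_mm, budget_b)
    }))
    matched <- purrr::map_dfr(seq_len(nrow(sites_truth)), function(i) {
      s <- sites_truth[i, ]
      hit <- dplyr::filter(found, .data$guide == s$guide,
                           .data$chrom == s$chrom,
                           .data$strand == s$strand,
                           .data$start == s$position)
      if (nrow(hit) != 1L ||
          hit$n_mismatches != s$n_mismatches ||
          hit$bulge_size != s$bulge_size) {
        abort(sprintf(
          "planted site %d not recovered at its stated budget on re-scan", i))
      }
      hit$occupancy <- s$occupancy
      hit$cut_fraction <- s$cut_fraction
      hit
    })
    sites <- new_sites_tibble(matched)
  }

  structure(list(genome = genome, contigs = contig_lengths(genome),
                 guides = guides, sites = sites, seed = seed,
                 gc_content = gc_content),
            class = "sim_genome")
}

overlaps_any <- function(mat, s, e) {
  if (is.null(mat) || nrow(mat) == 0) return(FALSE)
  any(mat[, 1] < e & mat[, 2] > s)
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("<sim_genome> %d contig(s), %s bp total, %d planted site(s), seed %d\n",
              length(x$genome), format(sum(x$contigs), big.mark = ","),
              nrow(x$sites), x$seed))
  invisible(x)
}
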