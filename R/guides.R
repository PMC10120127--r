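#' Define a guide RNA
#'
#' A guide RNA is described by its spacer (the 5'->3' protospacer-matching
#' sequence, typically 20 nt) and the protospacer-adjacent motif (PAM)
#' required 3' of the protospacer on the genomic site. The PAM may contain
#' IUPAC ambiguity codes; the SpCas9 default is `"NGG"`.
#'
#' @param name Short label for the guide.
#' @param spacer Spacer sequence 5'->3', alphabet ACGT.
#' @param pam PAM pattern with IUPAC codes, matched 3' of the protospacer.
#' @return An object of class `guide_rna` with fields `name`, `spacer`, `pam`.
#' @examples
#' guide_rna("sg1", "GCTTAATTAAGGTAAACGTC")
#' @export
guide_rna <- function(name, spacer, pam = "NGG") {
  stopifnot(is.character(name), length(name) == 1L)
  spacer <- toupper(spacer)
  pam <- toupper(pam)
  if (!nzchar(spacer) || grepl("[^ACGT]", spacer)) {
    abort("spacer must be a non-empty ACGT string")
  }
  if (!nzchar(pam)) abort("pam must be non-empty")
  pam_position_sets(pam)  # validates IUPAC codes
  if (nchar(spacer) < 4L) {
    abort("spacer shorter than 4 nt has no defined cut position")
  }
  structure(list(name = name, spacer = spacer, pam = pam),
            class = "guide_rna")
}

#' @export
print.guide_rna <- function(x, ...) {
  cat(sprintf("<guide_rna> %s: %s | PAM %s (%d nt spacer)\n",
              x$name, x$spacer, x$pam, nchar(x$spacer)))
  invisible(x)
}

#' Read a guide list from a tab-separated file
#'
#' Expects columns `name`, `spacer` and optionally `pam` (default NGG),
#' one guide per line, with or without a header line.
#'
#' @param path Path to the guide list.
#' @return A named list of [guide_rna()] objects.
#' @export
read_guides <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t|\\s+")
  if (length(parts) && identical(tolower(parts[[1]][1]), "name")) {
    parts <- parts[-1]
  }
  guides <- lapply(parts, function(p) {
    if (length(p) < 2L) abort(sprintf("malformed guide line: '%s'", paste(p, collapse = " ")))
    guide_rna(p[1], p[2], if (length(p) >= 3L) p[3] else "NGG")
  })
  setNames(guides, vapply(guides, `[[`, character(1), "name"))
}

#' Count guanines exposed by R-loop formation
#'
#' Kethoxal labels unpaired guanines. When a Cas9/dCas9 R-loop forms, the
#' strand displaced as ssDNA is the non-target strand, i.e. the strand whose
#' sequence equals the protospacer as written 5'->3'. The number of G bases
#' in that sequence therefore bounds the labelability of the site: a site
#' with zero exposed guanines is invisible to the assay.
#'
#' @param x A [guide_rna()], or a character vector of protospacer-strand
#'   sequences (spacers or matched site sequences).
#' @return Integer vector of exposed-G counts.
#' @examples
#' count_exposed_guanines("GCTTAATTAAGGTAAACGTC")  # 4
#' @export
count_exposed_guanines <- function(x) {
  if (inherits(x, "guide_rna")) x <- x$spacer
  as.integer(stringr::str_count(toupper(x), stringr::fixed("G")))
}

#' Census of exposed-G counts over all PAM-adjacent k-mers
#'
#' Scans both strands of a genome for PAM occurrences and tabulates the
#' exposed-G count of every adjacent protospacer-length window, e.g. to ask
#' what fraction of possible guides would be invisible to a
#' guanine-labeling assay.
#'
#' @param genome Named character vector of contig sequences.
#' @param spacer_length Protospacer length to census (default 20).
#' @param pam PAM pattern (default "NGG").
#' @return A tibble with one row per candidate site: `chrom`, `start`,
#'   `strand`, `n_g`, plus attribute-free columns suitable for summarising;
#'   the zero-G fraction is `mean(out$n_g == 0)`.
#' @export
exposed_g_census <- function(genome, spacer_length = 20L, pam = "NGG") {
  dummy <- guide_rna("census", strrep("A", spacer_length), pam)
  hits <- find_sites(genome, dummy, max_mismatches = spacer_length)
  tibble::tibble(
    chrom = hits$chrom, start = hits$start, strand = hits$strand,
    n_g = count_exposed_guanines(hits$site_sequence)
  )
}
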