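# Shared low-level helpers: sequence encoding, IUPAC sets, seed derivation.

# Integer encoding A=1 C=2 G=3 T=4; anything else (incl. N) = 0 and never
# matches a spacer base or a PAM code.
BASES <- c("A", "C", "G", "T")

.base_lookup <- local({
  lk <- integer(256)
  lk[utf8ToInt("A") + 1L] <- 1L
  lk[utf8ToInt("C") + 1L] <- 2L
  lk[utf8ToInt("G") + 1L] <- 3L
  lk[utf8ToInt("T") + 1L] <- 4L
  lk[utf8ToInt("a") + 1L] <- 1L
  lk[utf8ToInt("c") + 1L] <- 2L
  lk[utf8ToInt("g") + 1L] <- 3L
  lk[utf8ToInt("t") + 1L] <- 4L
  lk
})

encode_seq <- function(x) {
  .base_lookup[as.integer(charToRaw(x)) + 1L]
}

decode_seq <- function(code) {
  paste(c("N", BASES)[code + 1L], collapse = "")
}

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# One logical(5) per pattern position, indexed by code + 1; code 0 (ambiguous
# genome base) is always FALSE so genomic N never satisfies a PAM position.
pam_position_sets <- function(pam) {
  chars <- strsplit(toupper(pam), "")[[1]]
  bad <- setdiff(chars, names(IUPAC_SETS))
  if (length(bad)) {
    abort(paste0("invalid IUPAC code(s) in PAM pattern: ",
                 paste(unique(bad), collapse = ", ")))
  }
  lapply(chars, function(ch) {
    ok <- logical(5)
    ok[match(IUPAC_SETS[[ch]], BASES) + 1L] <- TRUE
    ok
  })
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

revcomp_code <- function(code) {
  rev(c(0L, 4L, 3L, 2L, 1L)[code + 1L])
}

# Deterministic stream seeds derived from a master seed; kept below 2^31 so
# they stay valid R integers.
derive_seed <- function(seed, ...) {
  ids <- c(...)
  s <- as.double(seed) %% 2147483629
  for (k in ids) {
    s <- (s * 48271 + as.double(k) + 1) %% 2147483629
  }
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Contig registry: named integer-ish vector of lengths.
contig_lengths <- function(genome) {
  if (is.numeric(genome)) return(genome)
  vapply(genome, nchar, numeric(1))
}

check_contigs <- function(records, contigs) {
  bad <- !records$chrom %in% names(contigs)
  if (any(bad)) {
    abort(paste0("records reference contigs absent from the reference: ",
                 paste(unique(records$chrom[bad]), collapse = ", ")))
  }
  lens <- unname(contigs[records$chrom])
  out <- which(records$start < 0 | records$end > lens | records$start >= records$end)
  if (length(out)) {
    i <- out[1]
    abort(sprintf("record %d (%s:%d-%d) falls outside its contig bounds",
                  i, records$chrom[i], records$start[i], records$end[i]))
  }
  invisible(TRUE)
}
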