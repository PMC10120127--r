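# End-to-end workflows tying the stages together: simulate a dataset,
# analyze a dataset (profiles -> peaks -> curation -> annotation ->
# quantification -> ranked report), and run the saturation analysis.
# Each workflow writes a self-describing output directory when asked.

#' Default analysis parameters
#'
#' Every tunable of the analysis stages with its default; used by
#' [caskas_analyze()] and overridable via a YAML config or `...`.
#' @return Named list of defaults.
#' @export
default_params <- function() {
  list(
    max_mismatches = 4L, max_bulge = 0L,
    peak_window = 300L, peak_step = 100L, peak_min_q = 0.01,
    asymmetry_half_window = 100L, asymmetry_threshold = 0.5,
    annotate_max_distance = 500L,
    flank = 500L,
    classify_window = 50L, classify_n_perm = 2000L,
    classify_quantile = 0.999, classify_min_rpm = 1,
    read_length = 36L, seed = 1L
  )
}

#' Load a run configuration from YAML
#'
#' Flat key-value YAML; unknown keys are reported, missing keys take the
#' defaults from [default_params()]. All validation problems are listed at
#' once.
#'
#' @param path YAML path, or `NULL` for pure defaults.
#' @param overrides Named list applied after the file.
#' @return Named list of resolved parameters.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  params <- default_params()
  given <- if (!is.null(path)) yaml::read_yaml(path) else list()
  given <- utils::modifyList(given, overrides)
  problems <- character()
  unknown <- setdiff(names(given), names(params))
  if (length(unknown)) {
    problems <- c(problems, paste0("unknown parameter(s): ",
                                   paste(unknown, collapse = ", ")))
  }
  params <- utils::modifyList(params, given[intersect(names(given), names(params))])
  if (params$peak_window < 10) problems <- c(problems, "peak_window must be >= 10")
  if (params$asymmetry_half_window < 25) {
    problems <- c(problems, "asymmetry_half_window must be >= 25")
  }
  if (params$flank <= 0) problems <- c(problems, "flank must be positive")
  if (length(problems)) abort(paste(problems, collapse = "; "))
  params
}

#' Analyze a CasKAS-style dataset end to end
#'
#' Builds deduplicated profiles, calls and curates peaks, scans the genome
#' for predicted guide target sites, annotates peaks against them, and
#' quantifies every predicted site (windowed RPM occupancy, treatment-
#' minus-control RPM for in vivo runs, maximal C-score and cut-vs-bind
#' call), returning a report ranked by occupancy.
#'
#' @param reads A [read_set()] or path to BED/SAM alignments.
#' @param genome Named character vector of contigs, or FASTA path.
#' @param guides A [guide_rna()] or named list of them (or guide-list path).
#' @param control Optional no-guide control (`read_set` or path); required
#'   when `mode = "in_vivo"`.
#' @param mode `"in_vitro"` or `"in_vivo"`.
#' @param nuclease `"dcas9"` or `"cas9"`; cut calls are only made for cas9.
#' @param blacklist Optional blacklist intervals (tibble or BED path).
#' @param params Parameter list from [load_run_config()]/[default_params()].
#' @param outdir Optional output directory; when given, tracks (bedGraph),
#'   peaks and sites (BED), the report (TSV) and a resolved-config manifest
#'   are written.
#' @return Object of class `caskas_report`: list with `report` (ranked
#'   per-site tibble), `peaks` (curated, annotated), `sites`, `profiles`,
#'   `params`.
#' @export
caskas_analyze <- function(reads, genome, guides, control = NULL,
                           mode = c("in_vitro", "in_vivo"),
                           nuclease = c("dcas9", "cas9"),
                           blacklist = NULL, params = default_params(),
                           outdir = NULL) {
  mode <- match.arg(mode)
  nuclease <- match.arg(nuclease)
  if (is.character(genome) && length(genome) == 1L && is.null(names(genome))) {
    genome <- read_genome_fasta(genome)
  }
  if (inherits(guides, "guide_rna")) guides <- setNames(list(guides), guides$name)
  if (is.character(guides)) guides <- read_guides(guides)
  if (is.character(reads)) {
    reads <- load_alignments(reads, genome, read_length = params$read_length)
  }
  if (mode == "in_vivo" && is.null(control)) {
    abort("in_vivo mode requires a no-guide control library")
  }
  if (is.character(control)) {
    control <- load_alignments(control, genome, read_length = params$read_length)
  }
  if (is.character(blacklist)) blacklist <- read_bed_intervals(blacklist)

  fp <- fiveprime_profile(reads)
  peaks <- call_peaks(reads, window = params$peak_window,
                      step = params$peak_step, min_q = params$peak_min_q)
  peaks <- filter_blacklist(peaks, blacklist)
  peaks <- curate_peaks(peaks, fp, half_window = params$asymmetry_half_window,
                        threshold = params$asymmetry_threshold)

  sites <- dplyr::bind_rows(lapply(guides, function(g) {
    find_sites(genome, g, params$max_mismatches, params$max_bulge)
  }))
  sites <- new_sites_tibble(sites)
  peaks <- annotate_peaks(peaks, sites,
                          max_distance = params$annotate_max_distance)

  report <- tibble::as_tibble(sites)
  report$rpm_ot <- rpm_ot(reads, sites, flank = params$flank)
  if (!is.null(control)) {
    report$rpm_diff <- rpm_diff(reads, control, sites, flank = params$flank)
  }
  cls <- classify_cut_vs_bind(
    reads, fp, sites, window = params$classify_window,
    n_perm = params$classify_n_perm,
    null_quantile = params$classify_quantile,
    min_rpm = params$classify_min_rpm, flank = params$flank,
    seed = params$seed)
  report$c_score_max <- cls$c_score_max
  report$c_score_pos <- cls$c_score_pos
  report$cut_call <- if (nuclease == "cas9") cls$cut_call else "not_assessed"
  report <- dplyr::arrange(report, dplyr::desc(.data$rpm_ot), .data$chrom,
                           .data$start)
  report$rank <- seq_len(nrow(report))
  report <- dplyr::select(report, -"mismatch_offsets")

  out <- structure(list(report = report, peaks = peaks, sites = sites,
                        fiveprime = fp, reads = reads, params = params,
                        mode = mode, nuclease = nuclease),
                   class = "caskas_report")
  if (!is.null(outdir)) write_report_dir(out, outdir)
  out
}

#' @export
print.caskas_report <- function(x, ...) {
  cat(sprintf("<caskas_report> %s/%s: %d predicted site(s), %d peak(s) (%d pass curation)\n",
              x$mode, x$nuclease, nrow(x$report), nrow(x$peaks),
              sum(x$peaks$curation_pass %||% FALSE)))
  invisible(x)
}

#' @exportS3Method
tidy.caskas_report <- function(x, ...) x$report

#' @exportS3Method
glance.caskas_report <- function(x, ...) {
  tibble::tibble(
    n_sites = nrow(x$report), n_peaks = nrow(x$peaks),
    n_peaks_curated = sum(x$peaks$curation_pass),
    n_predicted_peaks = attr(x$peaks, "n_predicted") %||% NA_integer_,
    n_novel_peaks = attr(x$peaks, "n_novel") %||% NA_integer_,
    n_cut_calls = sum(x$report$cut_call == "cut"),
    library_size = x$reads$library_size)
}

write_report_dir <- function(x, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  readr::write_tsv(x$report, file.path(outdir, "report.tsv"))
  write_peaks_bed(x$peaks, file.path(outdir, "peaks.bed"))
  write_sites_bed(x$sites, file.path(outdir, "sites.bed"))
  write_bedgraph(x$fiveprime, file.path(outdir, "fiveprime_plus.bedGraph"), "plus")
  write_bedgraph(x$fiveprime, file.path(outdir, "fiveprime_minus.bedGraph"), "minus")
  cs <- c_score_track(x$fiveprime)
  csp <- new_profile(lapply(cs$values, function(v) list(plus = v, minus = numeric(length(v)))),
                     cs$contigs, "c_score", cs$library_size)
  write_bedgraph(csp, file.path(outdir, "c_score.bedGraph"), "plus")
  manifest <- c(list(package = "crisprkas", mode = x$mode,
                     nuclease = x$nuclease,
                     library_size = x$reads$library_size), x$params)
  writeLines(yaml::as.yaml(manifest), file.path(outdir, "manifest.yaml"))
  invisible(outdir)
}

#' Run the saturation analysis as a workflow step
#'
#' @inheritParams saturation_analysis
#' @param outdir Optional directory to write `saturation.tsv` into.
#' @return A `saturation_result`.
#' @export
caskas_saturate <- function(reads, sites, fractions = c(0.05, 0.1, 0.2, 0.35,
                                                        0.5, 0.75, 1),
                            n_sets = 10L, tolerance = 0.2, flank = 500L,
                            seed = 1L, outdir = NULL) {
  res <- saturation_analysis(reads, sites, fractions, n_sets = n_sets,
                             tolerance = tolerance, flank = flank, seed = seed)
  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    readr::write_tsv(res$table, file.path(outdir, "saturation.tsv"))
  }
  res
}
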