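test_that("a 50x-enriched planted site yields exactly one peak containing it", {
  for (seed in c(101, 102, 103)) {
    hs <- make_small_sim(seed = seed, n_sites = 1, genome_len = 100000,
                         n_fragments = 20000, background_rate = 0.9)
    frags <- simulate_fragments(hs$cfg, seed = seed + 1)
    rs <- read_set(frags, hs$sim$contigs)
    peaks <- call_peaks(rs, min_q = 0.01)
    site <- hs$sim$sites[1, ]
    expect_equal(nrow(peaks), 1L)
    expect_true(peaks$start <= site$start && peaks$end >= site$end)
    expect_true(abs(peaks$summit - (site$start + site$end) / 2) < 300)
  }
})

test_that("pure background yields no peaks and calibrated window p-values", {
  fp_rates <- sapply(c(111, 112, 113), function(seed) {
    hs <- make_small_sim(seed = seed, n_sites = 1, genome_len = 100000,
                         n_fragments = 20000, background_rate = 1)
    frags <- simulate_fragments(hs$cfg, seed = seed)
    rs <- read_set(frags, hs$sim$contigs)
    expect_equal(nrow(call_peaks(rs, min_q = 0.01)), 0L)
    w <- score_windows(rs)
    mean(w$p_value < 0.05)
  })
  expect_true(all(fp_rates <= 0.1))  # <= 2 * alpha, conservative by design
})

test_that("peak location is stable when depth doubles", {
  hs <- make_small_sim(seed = 121, n_sites = 1, genome_len = 100000,
                       n_fragments = 20000, background_rate = 0.9)
  hs2 <- make_small_sim(seed = 121, n_sites = 1, genome_len = 100000,
                        n_fragments = 40000, background_rate = 0.9)
  p1 <- call_peaks(read_set(simulate_fragments(hs$cfg, seed = 5),
                            hs$sim$contigs))
  p2 <- call_peaks(read_set(simulate_fragments(hs2$cfg, seed = 6),
                            hs2$sim$contigs))
  expect_equal(nrow(p1), 1L)
  expect_equal(nrow(p2), 1L)
  expect_lt(abs(p1$summit - p2$summit), 25L)
})

test_that("blacklist filtering uses any-overlap and matches a brute-force oracle", {
  peaks <- crisprkas:::new_peaks_tibble(tibble::tibble(
    chrom = "chr1", start = c(100L, 500L, 900L), end = c(200L, 600L, 1000L),
    summit = c(150L, 550L, 950L), n_windows = 1L, count = 10L,
    fold_enrichment = 5, p_value = 1e-6, q_value = 1e-5))
  expect_equal(nrow(filter_blacklist(peaks, NULL)), 3L)
  expect_equal(nrow(filter_blacklist(peaks, peaks[0, c("chrom", "start", "end")])), 3L)

  # blacklist covering only the summit of the middle peak removes it
  bl <- tibble::tibble(chrom = "chr1", start = 550L, end = 551L)
  kept <- filter_blacklist(peaks, bl)
  expect_equal(kept$start, c(100L, 900L))
  expect_equal(attr(kept, "n_removed"), 1L)

  withr::with_seed(140, {
    rp <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 50, TRUE),
                         start = sample(0:5000, 50))
    rp$end <- rp$start + sample(50:300, 50, TRUE)
    rb <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 20, TRUE),
                         start = sample(0:5000, 20))
    rb$end <- rb$start + sample(20:400, 20, TRUE)
  })
  rp <- crisprkas:::new_peaks_tibble(dplyr::mutate(
    rp, summit = start, n_windows = 1L, count = 1L,
    fold_enrichment = 1, p_value = 0.5, q_value = 0.5))
  got <- filter_blacklist(rp, rb)
  brute <- sapply(seq_len(nrow(rp)), function(i) {
    !any(rb$chrom == rp$chrom[i] & rb$start < rp$end[i] & rb$end > rp$start[i])
  })
  expect_equal(got$start, rp$start[brute])
  # idempotence
  expect_equal(nrow(filter_blacklist(got, rb)), nrow(got))
})

test_that("asymmetry score hits its extreme, symmetric and swapped cases", {
  contigs <- c(chr1 = 2000L)
  prof <- crisprkas:::new_profile(
    list(chr1 = list(plus = numeric(2000), minus = numeric(2000))),
    contigs, "fiveprime", 100L)
  # all plus mass strictly left of 1000, all minus strictly right
  prof$values$chr1$plus[950:999] <- 1
  prof$values$chr1$minus[1002:1051] <- 1
  sc <- asymmetry_score(prof, "chr1", 900L, 1100L, half_window = 100L)
  expect_equal(sc$score, 1)
  expect_true(sc$anchor %in% 999:1001)

  # strand-symmetric pileup scores 0 at its center
  sym <- crisprkas:::new_profile(
    list(chr1 = list(plus = numeric(2000), minus = numeric(2000))),
    contigs, "fiveprime", 100L)
  sym$values$chr1$plus[950:1050] <- 1
  sym$values$chr1$minus[950:1050] <- 1
  sc_center <- asymmetry_score(sym, "chr1", 1000L, 1000L, half_window = 100L)
  expect_equal(sc_center$score, 0)

  # swapping strands negates the score at the same anchor
  swp <- prof
  swp$values$chr1$plus <- prof$values$chr1$minus
  swp$values$chr1$minus <- prof$values$chr1$plus
  p <- 1000L
  direct <- asymmetry_score(prof, "chr1", p, p, half_window = 100L)$score
  swapped <- asymmetry_score(swp, "chr1", p, p, half_window = 100L)$score
  expect_equal(swapped, -direct)

  # zero mass everywhere: flagged, not scored
  zero <- crisprkas:::new_profile(
    list(chr1 = list(plus = numeric(2000), minus = numeric(2000))),
    contigs, "fiveprime", 100L)
  scz <- asymmetry_score(zero, "chr1", 900L, 1100L)
  expect_true(is.na(scz$score))
  expect_false(scz$scored)

  expect_error(asymmetry_score(prof, "chr1", 900L, 1100L, half_window = 10L),
               "half_window")
})

test_that("simulated dCas9 sites pass curation while background windows do not", {
  hs <- make_small_sim(seed = 131, n_sites = 1, genome_len = 100000,
                       n_fragments = 30000, background_rate = 0.8)
  frags <- simulate_fragments(hs$cfg, seed = 9)
  rs <- read_set(frags, hs$sim$contigs)
  fp <- fiveprime_profile(rs)
  site <- hs$sim$sites[1, ]
  sc <- asymmetry_score(fp, site$chrom, site$start - 100L, site$end + 100L,
                        half_window = 300L)
  expect_gt(sc$score, 0.9)
  # background windows far from the site
  far <- setdiff(seq(5000, 95000, by = 10000), 0)
  far <- far[abs(far - site$start) > 2000]
  bg_scores <- sapply(far, function(p) {
    asymmetry_score(fp, site$chrom, p, p + 200L, half_window = 300L)$score
  })
  expect_lt(stats::median(abs(bg_scores)), 0.2)
})

test_that("peak annotation prefers near, low-mismatch sites and is idempotent", {
  sites <- crisprkas:::new_sites_tibble(tibble::tibble(
    guide = "g", chrom = "chr1", start = c(1000L, 1400L, 5000L),
    end = c(1020L, 1420L, 5020L), strand = "+",
    pam_start = c(1020L, 1420L, 5020L), pam_end = c(1023L, 1423L, 5023L),
    site_sequence = "x", n_mismatches = c(3L, 0L, 1L),
    mismatch_offsets = list(integer(), integer(), integer()),
    bulge_type = "none", bulge_size = 0L, bulge_offset = NA_integer_,
    cut_site = c(1017L, 1417L, 5017L)))
  peaks <- crisprkas:::new_peaks_tibble(tibble::tibble(
    chrom = "chr1", start = c(900L, 8000L), end = c(1600L, 8400L),
    summit = c(1217L, 8200L), n_windows = 1L, count = 5L,
    fold_enrichment = 3, p_value = 1e-5, q_value = 1e-4))
  ann <- annotate_peaks(peaks, sites, max_distance = 500L)
  expect_equal(ann$annotation, c("predicted_site", "novel"))
  expect_equal(ann$site_cut[1], 1417L)  # equidistant: 0-mm beats 3-mm
  expect_equal(attr(ann, "n_predicted"), 1L)
  expect_equal(attr(ann, "n_novel"), 1L)
  # summit exactly at a cut coordinate
  peaks$summit[2] <- 5017L
  ann2 <- annotate_peaks(peaks, sites, max_distance = 500L)
  expect_equal(ann2$annotation[2], "predicted_site")
  expect_equal(ann2$site_distance[2], 0L)
  # idempotent
  ann3 <- annotate_peaks(ann2, sites, max_distance = 500L)
  expect_equal(ann3$annotation, ann2$annotation)
})

test_that("planted predicted-budget and beyond-budget sites split predicted vs novel", {
  g <- guide_rna("sg1", "GCTTAATTAAGGTAAACGTC")
  planted <- tibble::tibble(
    n_mismatches = c(0L, 1L, 2L, 3L, 4L, 5L, 5L, 5L),
    strand = rep_len(c("+", "-"), 8),
    occupancy = rep(1, 8))
  sim <- make_genome(400000, 0.45, seed = 151, guides = g, planted = planted)
  cfg <- sim_config(sim, n_fragments = 60000, background_rate = 0.5)
  frags <- simulate_fragments(cfg, seed = 10)
  rs <- read_set(frags, sim$contigs)
  peaks <- call_peaks(rs)
  predicted <- find_sites(sim$genome, g, max_mismatches = 4)
  ann <- annotate_peaks(peaks, predicted, max_distance = 500L)
  truth <- sim$sites
  within_budget <- truth[truth$n_mismatches <= 4, ]
  beyond <- truth[truth$n_mismatches == 5, ]
  covered <- function(s) {
    any(ann$annotation == "predicted_site" &
          abs(ann$summit - s$cut_site) < 500)
  }
  expect_equal(sum(sapply(seq_len(nrow(within_budget)),
                          function(i) covered(within_budget[i, ]))), 5L)
  novel_hits <- sapply(seq_len(nrow(beyond)), function(i) {
    any(ann$annotation == "novel" & abs(ann$summit - beyond$cut_site[i]) < 500)
  })
  expect_equal(sum(novel_hits), 3L)
})
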