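sg1 <- guide_rna("sg1", "GCTTAATTAAGGTAAACGTC")

test_that("synthetic genomes are reproducible, GC-calibrated, and rescannable", {
  planted <- tibble::tibble(n_mismatches = c(0L, 1L, 2L, 0L, 3L),
                            strand = c("+", "-", "+", "-", "+"),
                            occupancy = c(10, 5, 2, 1, 1))
  sim1 <- make_genome(200000, 0.5, seed = 7, guides = sg1, planted = planted)
  sim2 <- make_genome(200000, 0.5, seed = 7, guides = sg1, planted = planted)
  expect_identical(sim1$genome, sim2$genome)
  sim3 <- make_genome(200000, 0.5, seed = 8, guides = sg1, planted = planted)
  expect_false(identical(sim1$genome, sim3$genome))

  gc <- mean(strsplit(sim1$genome[[1]], "")[[1]] %in% c("G", "C"))
  expect_gt(gc, 0.49); expect_lt(gc, 0.51)

  expect_equal(nrow(sim1$sites), 5L)
  expect_equal(sort(sim1$sites$n_mismatches), c(0L, 0L, 1L, 2L, 3L))
  # re-scan at each site's own budget finds it
  for (i in seq_len(nrow(sim1$sites))) {
    s <- sim1$sites[i, ]
    hits <- find_sites(sim1$genome, sg1, s$n_mismatches)
    expect_true(any(hits$start == s$start & hits$strand == s$strand))
  }
})

test_that("fragment lengths, bubble overlap and asymmetry match the labeling model", {
  hs <- make_small_sim(seed = 5, n_sites = 1, background_rate = 0,
                       n_fragments = 10000)
  frags <- simulate_fragments(hs$cfg, seed = 11)
  site <- hs$sim$sites[1, ]
  expect_true(all(frags$origin == "site_binding"))
  # every fragment overlaps the R-loop bubble (the protospacer interval)
  expect_true(all(frags$start < site$end & frags$end > site$start))
  # fragment-length marginal is uniform on [150, 400]
  lens <- frags$end - frags$start
  expect_gte(min(lens), 150); expect_lte(max(lens), 400)
  ks <- suppressWarnings(stats::ks.test(lens, function(q) {
    stats::punif(q, 150, 401)
  }))
  expect_gt(ks$p.value, 0.01)
  # canonical asymmetry: plus 5' ends left, minus 5' ends right
  rs <- read_set(frags, hs$sim$contigs)
  fp <- fiveprime_profile(rs)
  sc <- asymmetry_score(fp, site$chrom, site$start - 200L, site$end + 200L,
                        half_window = 300L)
  expect_gt(sc$score, 0.9)
})

test_that("a zero-exposed-G bubble yields no site-derived signal", {
  # guide whose protospacer strand has no G: all-T spacer, planted exactly
  gt <- guide_rna("noG", strrep("T", 20))
  sim <- make_genome(30000, 0.45, seed = 9, guides = gt,
                     planted = tibble::tibble(n_mismatches = 0L, strand = "+",
                                              occupancy = 1))
  expect_equal(count_exposed_guanines(sim$sites$site_sequence), 0L)
  cfg <- sim_config(sim, n_fragments = 5000, background_rate = 0)
  frags <- simulate_fragments(cfg, seed = 1)
  expect_equal(nrow(frags), 0L)
})

test_that("capture counts scale with occupancy (10:1 within 3 SD)", {
  hs <- make_small_sim(seed = 6, n_sites = 2, background_rate = 0,
                       n_fragments = 44000, occupancy = c(10, 1))
  frags <- simulate_fragments(hs$cfg, seed = 2)
  sites <- hs$sim$sites
  n1 <- sum(frags$start < sites$end[1] & frags$end > sites$start[1])
  n2 <- sum(frags$start < sites$end[2] & frags$end > sites$start[2])
  # attempts are allocated 10:1; capture probability is equal for equal-G
  # sites, so compare against the attempt allocation with binomial noise
  expect_gt(n1 / n2, 10 - 3 * sqrt(1 / n1 + 1 / n2) * 10)
  expect_lt(n1 / n2, 10 + 3 * sqrt(1 / n1 + 1 / n2) * 10)
})

test_that("cleavage phases 5' ends: one blunt target-strand position, 2-3 staggered", {
  hs <- make_small_sim(seed = 8, n_sites = 1, background_rate = 0,
                       n_fragments = 20000, nuclease = "cas9",
                       cut_fraction = 1)
  frags <- simulate_fragments(hs$cfg, seed = 3)
  site <- hs$sim$sites[1, ]
  expect_setequal(unique(frags$origin),
                  c("site_cleaved_left", "site_cleaved_right"))
  cut <- site$cut_site
  expect_equal(site$strand, "+")
  # minus-strand (target) 5' ends: left pieces end at the blunt cut, except
  # the minority of sonication fragments that never reach the cut
  left_ends <- frags$end[frags$origin == "site_cleaved_left"] - 1L
  expect_gt(mean(left_ends == cut - 1L), 0.8)
  expect_equal(as.integer(sort(-table(left_ends))[1] * -1),
               as.integer(sum(left_ends == cut - 1L)))
  # plus-strand (non-target) 5' ends: 3 staggered positions at the
  # configured offsets, with frequencies ordered by the configured weights
  right_starts <- frags$start[frags$origin == "site_cleaved_right"]
  stagger <- site$pam_start - c(3L, 4L, 5L)
  expect_gt(mean(right_starts %in% stagger), 0.8)
  tab <- table(right_starts)[as.character(stagger)]
  expect_true(all(diff(as.numeric(tab)) < 0))  # weights 0.5 > 0.3 > 0.2
})

test_that("cut_fraction interpolates between pure binding and full cleavage", {
  fp_sharpness <- function(cut_fraction, seed) {
    hs <- make_small_sim(seed = 12, n_sites = 1, background_rate = 0,
                         n_fragments = 8000, nuclease = "cas9",
                         cut_fraction = cut_fraction)
    frags <- simulate_fragments(hs$cfg, seed = seed)
    rs <- read_set(frags, hs$sim$contigs, dedup = FALSE)
    fp <- fiveprime_profile(rs)
    v <- fp$values[[1]]
    max(oracle_c_score(v$plus, v$minus))
  }
  s0 <- fp_sharpness(0, 21)
  s5 <- fp_sharpness(0.5, 21)
  s1 <- fp_sharpness(1, 21)
  expect_lt(s0, s5)
  expect_lt(s5, s1)
})

test_that("uniform background passes a chi-square uniformity check", {
  hs <- make_small_sim(seed = 15, n_sites = 1, background_rate = 1,
                       n_fragments = 50000, genome_len = 50000)
  frags <- simulate_fragments(hs$cfg, seed = 4)
  expect_true(all(frags$origin == "background"))
  mid <- (frags$start + frags$end) / 2
  bins <- cut(mid, seq(1000, 49000, length.out = 25))
  counts <- table(bins)
  chi <- stats::chisq.test(counts)
  expect_gt(chi$p.value, 0.001)
})

test_that("in vivo active intervals are covered at the configured fold", {
  g <- guide_rna("sg1", "GCTTAATTAAGGTAAACGTC")
  sim <- make_genome(100000, 0.45, seed = 16, guides = g,
                     planted = tibble::tibble(n_mismatches = 0L, occupancy = 1))
  act <- tibble::tibble(chrom = "sim1", start = 60000L, end = 70000L)
  cfg <- sim_config(sim, n_fragments = 100000, background_rate = 1,
                    mode = "in_vivo", active_intervals = act, active_fold = 5)
  frags <- simulate_fragments(cfg, seed = 5)
  rs <- read_set(frags, sim$contigs, dedup = FALSE)
  cov <- coverage_profile(rs, mode = "per_fragment")$values[[1]]$plus
  inside <- mean(cov[61000:69000])
  outside <- mean(cov[c(5000:55000)])
  ratio <- inside / outside
  expect_gt(ratio, 4); expect_lt(ratio, 6)
})

test_that("the no-guide control contains background only, and in expectation matches treatment off-site", {
  hs <- make_small_sim(seed = 18, n_sites = 2, background_rate = 0.5,
                       n_fragments = 20000)
  res <- simulate_experiment(hs$cfg, seed = 6, with_control = TRUE)
  expect_false(any(grepl("^site", res$control$origin)))
  expect_true(any(grepl("^site", res$treatment$origin)))
  # off-site background rates agree between treatment and control
  n_bg_treat <- sum(res$treatment$origin == "background")
  n_bg_ctrl <- sum(res$control$origin == "background")
  expect_lt(abs(n_bg_treat - n_bg_ctrl), 4 * sqrt(n_bg_treat + 1))
})

test_that("duplicate resampling adds the expected duplicated fraction", {
  hs <- make_small_sim(seed = 19, n_sites = 1, background_rate = 1,
                       n_fragments = 100000, duplicate_rate = 0.2)
  frags <- simulate_fragments(hs$cfg, seed = 7)
  rs <- read_set(frags, hs$sim$contigs, dedup = TRUE)
  removed <- rs$n_duplicates_removed
  # ~ 20,000 resampled rows plus a few hundred coincidental collisions of
  # uniform fragments at this depth
  expect_gt(removed, 19200)
  expect_lt(removed, 21500)
})

test_that("simulation output round-trips and is byte-stable under the seed", {
  hs <- make_small_sim(seed = 20, n_sites = 2, background_rate = 0.4,
                       n_fragments = 2000)
  res <- simulate_experiment(hs$cfg, seed = 8, with_control = TRUE)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_simulation(res, d1)
  res_again <- simulate_experiment(hs$cfg, seed = 8, with_control = TRUE)
  p2 <- write_simulation(res_again, d2)
  for (nm in names(p1)) {
    expect_identical(unname(tools::md5sum(p1[[nm]])),
                     unname(tools::md5sum(p2[[nm]])), label = nm)
  }
  res_other <- simulate_experiment(hs$cfg, seed = 9, with_control = TRUE)
  d3 <- withr::local_tempdir()
  p3 <- write_simulation(res_other, d3)
  expect_false(identical(unname(tools::md5sum(p1[["fragments"]])),
                         unname(tools::md5sum(p3[["fragments"]]))))

  # BED round trip reproduces the in-memory fragment records exactly
  rt <- read_bed_intervals(p1[["fragments"]])
  expect_equal(rt$chrom, res$treatment$chrom)
  expect_equal(rt$start, res$treatment$start)
  expect_equal(rt$end, res$treatment$end)

  # FASTA round trip
  genome_rt <- read_genome_fasta(p1[["genome"]])
  expect_identical(genome_rt, hs$sim$genome)

  # emitted SAM passes format validation (conversion parses all records)
  skip_if_not_installed("Rsamtools")
  rs_sam <- load_alignments(p1[["sam"]], hs$sim$contigs, format = "sam",
                            dedup = FALSE)
  expect_equal(nrow(rs_sam$records), nrow(res$treatment))
  expect_true(all(rs_sam$records$strand == "."))
})
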