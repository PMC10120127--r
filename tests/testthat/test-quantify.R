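contigs <- c(chr1 = 100000L)

fake_site <- function(cut, chrom = "chr1") {
  tibble::tibble(chrom = chrom, cut_site = as.integer(cut))
}

test_that("windowed occupancy follows the RPM formula exactly", {
  # 50 stranded reads overlapping the window, library size forced to 1e6 by
  # padding with distant reads
  withr::with_seed(201, {
    near <- tibble::tibble(chrom = "chr1",
                           start = sample(9500:10400, 50, TRUE))
  })
  near$end <- near$start + 60L
  far <- tibble::tibble(chrom = "chr1",
                        start = seq(50000L, 90000L, length.out = 999950),
                        end = seq(50000L, 90000L, length.out = 999950) + 36L)
  far$start <- as.integer(far$start); far$end <- as.integer(far$end)
  rs <- read_set(dplyr::bind_rows(near, far) |>
                   dplyr::mutate(strand = "+"), contigs, dedup = FALSE)
  expect_equal(rs$library_size, 1000000L)
  expect_equal(rpm_ot(rs, fake_site(10000L), flank = 500L), 50)
  expect_equal(rpm_ot(rs, fake_site(25000L), flank = 500L), 0)
})

test_that("occupancy equals the brute-force overlap oracle on random input", {
  withr::with_seed(202, {
    df <- tibble::tibble(chrom = "chr1", start = sample(0:99000, 4000, TRUE),
                         strand = sample(c("+", "-", "."), 4000, TRUE))
    df$end <- df$start + sample(150:400, 4000, TRUE)
    sites <- fake_site(sample(2000:98000, 25))
  })
  rs <- read_set(df, contigs, dedup = FALSE)
  expect_equal(rpm_ot(rs, sites), oracle_rpm_ot(rs, sites))
})

test_that("rpm_diff is antisymmetric, zero on identical libraries", {
  withr::with_seed(203, {
    df <- tibble::tibble(chrom = "chr1", start = sample(0:99000, 2000, TRUE))
  })
  df$end <- df$start + 200L
  a <- read_set(df, contigs)
  sites <- fake_site(c(10000L, 50000L))
  expect_equal(rpm_diff(a, a, sites), c(0, 0))
  withr::with_seed(204, {
    df2 <- tibble::tibble(chrom = "chr1", start = sample(0:99000, 2000, TRUE))
  })
  df2$end <- df2$start + 200L
  b <- read_set(df2, contigs)
  expect_equal(rpm_diff(a, b, sites), -rpm_diff(b, a, sites))
  empty <- read_set(df[0, ], contigs)
  expect_error(rpm_diff(a, empty, sites), "non-empty")
})

test_that("treatment minus control is positive at the site and ~0 elsewhere", {
  hs <- make_small_sim(seed = 211, n_sites = 1, genome_len = 100000,
                       n_fragments = 40000, background_rate = 0.7)
  res <- simulate_experiment(hs$cfg, seed = 11, with_control = TRUE)
  tr <- read_set(res$treatment, hs$sim$contigs)
  ct <- read_set(res$control, hs$sim$contigs)
  site <- hs$sim$sites[1, ]
  at_site <- rpm_diff(tr, ct, fake_site(site$cut_site, site$chrom))
  expect_gt(at_site, 0)
  off <- fake_site(setdiff(seq(10000, 90000, 20000),
                           (site$cut_site - 5000):(site$cut_site + 5000)),
                   site$chrom)
  offs <- rpm_diff(tr, ct, off)
  expect_lt(max(abs(offs)), at_site / 10)
})

test_that("the C-score track reproduces the 3-bp window product by hand and by oracle", {
  prof <- crisprkas:::new_profile(
    list(chr1 = list(plus = numeric(1000), minus = numeric(1000))),
    c(chr1 = 1000L), "fiveprime", 10L)
  prof$values$chr1$plus[101] <- 5    # position 100
  prof$values$chr1$minus[101] <- 4
  cs <- c_score_track(prof)
  v <- cs$values$chr1
  expect_equal(v[100:102], rep(20, 3))  # positions 99-101
  expect_equal(sum(v != 0), 3L)

  # zero minus strand kills the product everywhere
  prof0 <- prof
  prof0$values$chr1$minus[] <- 0
  expect_equal(sum(c_score_track(prof0)$values$chr1), 0)

  # random tracks match the double-loop oracle bit for bit, edges included
  for (seed in 1:5) {
    withr::with_seed(seed, {
      p <- numeric(300); m <- numeric(300)
      p[sample(300, 40)] <- runif(40) * 9
      m[sample(300, 40)] <- runif(40) * 9
    })
    prof$values$chr1 <- list(plus = c(p, numeric(700)),
                             minus = c(m, numeric(700)))
    got <- c_score_track(prof)$values$chr1[1:300]
    expect_identical(got, oracle_c_score(p, m))
  }
  expect_error(c_score_track(coverage_profile(
    read_set(tibble::tibble(chrom = "chr1", start = 1L, end = 100L),
             c(chr1 = 1000L)), "per_read")), "5'-end")
})

test_that("cut sites are separated from bind-only sites at matched occupancy", {
  g <- guide_rna("sg1", "GCTTAATTAAGGTAAACGTC")
  planted <- tibble::tibble(
    n_mismatches = 0L, strand = rep_len(c("+", "-"), 4),
    occupancy = rep(1, 4), cut_fraction = c(0.9, 0, 0.9, 0))
  sim <- make_genome(200000, 0.45, seed = 221, guides = g, planted = planted)
  cfg <- sim_config(sim, n_fragments = 100000, background_rate = 0.2,
                    nuclease = "cas9")
  frags <- simulate_fragments(cfg, seed = 12)
  rs <- read_set(frags, sim$contigs)
  fp <- fiveprime_profile(rs)
  cls <- classify_cut_vs_bind(rs, fp, sim$sites, n_perm = 500, seed = 13)
  expect_equal(cls$cut_call[sim$sites$cut_fraction > 0], c("cut", "cut"))
  expect_equal(cls$cut_call[sim$sites$cut_fraction == 0],
               c("bind_only", "bind_only"))
  # occupancy floor: a site with no signal is undetermined
  lowocc <- classify_cut_vs_bind(rs, fp, fake_site(5000L, "sim1"),
                                 n_perm = 100, min_rpm = 5000)
  expect_equal(lowocc$cut_call, "undetermined")
})

test_that("replicate agreement is 1 for identical, ~0 for shuffled replicates", {
  withr::with_seed(231, x <- rexp(100) * 50)
  ra <- replicate_agreement(x, x)
  expect_equal(ra$pearson, 1)
  expect_equal(ra$spearman, 1)
  withr::with_seed(232, y <- sample(x))
  shuf <- replicate_agreement(x, y)
  expect_lt(abs(shuf$spearman), 0.3)
  expect_error(replicate_agreement(x[1:2], x[1:2]), "3")
  expect_error(replicate_agreement(x, x[1:50]), "matched")

  g <- glance(ra)
  expect_equal(g$n_sites, 100L)
})

test_that("half-depth pseudo-replicates agree strongly on planted sites", {
  hs <- make_small_sim(seed = 241, n_sites = 6, genome_len = 200000,
                       n_fragments = 60000, background_rate = 0.3,
                       occupancy = 2^(5:0))
  frags <- simulate_fragments(hs$cfg, seed = 14)
  rs <- read_set(frags, hs$sim$contigs)
  r1 <- subsample(rs, 0.5, seed = 1)
  r2 <- subsample(rs, 0.5, seed = 2)
  a <- rpm_ot(r1, hs$sim$sites)
  b <- rpm_ot(r2, hs$sim$sites)
  expect_gt(replicate_agreement(a, b)$spearman, 0.9)
})

test_that("saturation is exact at fraction 1 and seeded-reproducible", {
  withr::with_seed(251, {
    df <- tibble::tibble(chrom = "chr1", start = sample(0:93000, 5000, TRUE))
  })
  df$end <- df$start + 250L
  rs <- read_set(df, contigs, dedup = FALSE)
  sites <- fake_site(seq(10000L, 90000L, 10000L))
  res <- saturation_analysis(rs, sites, fractions = c(0.3, 1), n_sets = 5,
                             seed = 31)
  at1 <- res$table[res$table$fraction == 1, ]
  expect_equal(at1$mean_within, 1)
  expect_equal(at1$sd_within, 0)
  res2 <- saturation_analysis(rs, sites, fractions = c(0.3, 1), n_sets = 5,
                              seed = 31)
  expect_identical(res$table, res2$table)
  # zero-occupancy sites are excluded and counted
  sites0 <- dplyr::bind_rows(sites, fake_site(98500L))
  res3 <- saturation_analysis(rs, sites0, fractions = 1, seed = 1)
  expect_equal(res3$n_zero_excluded, sum(rpm_ot(rs, sites0) == 0))
})
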