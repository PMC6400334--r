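test_that("config validation enforces rates, ploidy and site budget", {
  expect_error(sim_config(frac_diagnostic = 0.7, frac_ghost_private = 0.5),
               "exceed 1")
  expect_error(sim_config(ploidy = 5), "ploidy")
  expect_error(sim_config(fragment_error_rate = 1.2), "rates")
})

test_that("founder pools honour the site-class construction", {
  # degenerate config: every site diagnostic, no leak
  cfg <- sim_config(n_chrom = 1, n_sites_per_chrom = 300,
                    frac_diagnostic = 1, diagnostic_leak = 0,
                    frac_ghost_private = 0, seed = 2)
  f <- simulate_founders(cfg)
  expect_true(all(f$pools$E == 0L))
  expect_true(all(f$pools$A == 1L))
  expect_length(f$diag_sites, 300L)

  # determinism: same seed, identical pools
  f2 <- simulate_founders(cfg)
  expect_identical(f$pools, f2$pools)
  expect_identical(f$sites, f2$sites)

  # diagnostic-site count within binomial expectation of the fraction
  cfg3 <- sim_config(n_chrom = 1, n_sites_per_chrom = 2000,
                     frac_diagnostic = 0.3, seed = 5)
  f3 <- simulate_founders(cfg3)
  expect_lt(abs(length(f3$diag_sites) - 600), 3 * sqrt(2000 * 0.3 * 0.7))

  # ghost-private alleles absent from the source pools
  expect_true(all(f3$pools$E[, f3$ghost_sites] == 0L))
  expect_true(all(f3$pools$A[, f3$ghost_sites] == 0L))
})

test_that("admixed genomes carry the configured recombination structure", {
  # no meioses -> uniform ancestry per haplotype, no switches
  cfg0 <- sim_config(n_chrom = 2, n_sites_per_chrom = 300, n_meioses = 0,
                     frac_ghost_private = 0, loh_tract_rate = 0, seed = 3)
  f0 <- simulate_founders(cfg0)
  tr0 <- simulate_admixed_polyploid(f0, cfg0)
  expect_identical(sum(truth_switches(tr0)), 0L)

  # junction count Poisson around n_meioses * L_kb * cM/kb / 100
  cfg <- sim_config(n_chrom = 1, chrom_length = 1e6, n_sites_per_chrom = 100,
                    n_meioses = 10, loh_tract_rate = 0,
                    frac_ghost_private = 0, seed = 1)
  lam <- 10 * 1000 * 0.34 / 100                     # 34 per haplotype
  nx <- unlist(lapply(1:12, function(s) {
    cfgs <- sim_config(n_chrom = 1, chrom_length = 1e6,
                       n_sites_per_chrom = 100, n_meioses = 10,
                       loh_tract_rate = 0, frac_ghost_private = 0, seed = s)
    fs <- simulate_founders(cfgs)
    trs <- simulate_admixed_polyploid(fs, cfgs)
    lengths(trs$crossovers[[1]])
  }))
  expect_lt(abs(mean(nx) - lam), 3 * sqrt(lam / length(nx)))

  # switch count non-decreasing in n_meioses (in expectation over seeds)
  mean_sw <- vapply(c(2, 20), function(t) {
    mean(vapply(1:8, function(s) {
      cfgt <- sim_config(n_chrom = 1, n_sites_per_chrom = 400,
                         frac_diagnostic = 0.5, frac_ghost_private = 0,
                         loh_tract_rate = 0, n_meioses = t, seed = s)
      ft <- simulate_founders(cfgt)
      sum(truth_switches(simulate_admixed_polyploid(ft, cfgt)))
    }, numeric(1)))
  }, numeric(1))
  expect_gt(mean_sw[2], mean_sw[1])
})

test_that("LOH tracts copy donor alleles and are recorded", {
  cfg <- sim_config(n_chrom = 2, n_sites_per_chrom = 400,
                    loh_tract_rate = 0.01, seed = 8)
  f <- simulate_founders(cfg)
  tr <- simulate_admixed_polyploid(f, cfg)
  expect_gt(nrow(tr$loh), 0)
  # with the rate zeroed no tracts appear
  cfg0 <- sim_config(n_chrom = 2, n_sites_per_chrom = 400,
                     loh_tract_rate = 0, seed = 8)
  tr0 <- simulate_admixed_polyploid(simulate_founders(cfg0), cfg0)
  expect_identical(nrow(tr0$loh), 0L)
})

test_that("observations follow the read-count and fragment models", {
  # tetraploid site with 1 alt copy: alt fraction concentrates at 0.25
  cfg <- sim_config(n_chrom = 1, n_sites_per_chrom = 500, ploidy = 4,
                    short_read_depth_mean = 10000, fragment_count = 0,
                    loh_tract_rate = 0, seed = 4)
  f <- simulate_founders(cfg)
  tr <- simulate_admixed_polyploid(f, cfg)
  obs <- simulate_observations(tr, cfg)
  one_copy <- which(colSums(tr$alleles) == 1L)
  frac <- obs$alt[one_copy] / obs$depth[one_copy]
  expect_lt(max(abs(frac - 0.25)), 0.02)
  two_copy <- which(colSums(tr$alleles) == 2L)
  expect_lt(max(abs(obs$alt[two_copy] / obs$depth[two_copy] - 0.5)), 0.02)

  # noiseless fragments match their source haplotype exactly
  cfg0 <- sim_config(n_chrom = 1, n_sites_per_chrom = 300,
                     fragment_count = 200, fragment_error_rate = 0, seed = 6)
  f0 <- simulate_founders(cfg0)
  tr0 <- simulate_admixed_polyploid(f0, cfg0)
  obs0 <- simulate_observations(tr0, cfg0)
  src <- attr(obs0$fragments, "source")
  ok <- vapply(seq_along(obs0$fragments$reads), function(i) {
    r <- obs0$fragments$reads[[i]]
    all(r$allele == tr0$alleles[src$hap[i], r$idx])
  }, logical(1))
  expect_true(all(ok))

  # flip-event rate within 3 binomial sd of the configured error rate
  cfg2 <- sim_config(n_chrom = 1, n_sites_per_chrom = 500,
                     fragment_count = 1000, fragment_error_rate = 0.02,
                     seed = 7)
  f2 <- simulate_founders(cfg2)
  tr2 <- simulate_admixed_polyploid(f2, cfg2)
  obs2 <- simulate_observations(tr2, cfg2)
  src2 <- attr(obs2$fragments, "source")
  n_alle <- sum(vapply(obs2$fragments$reads, function(r) length(r$idx),
                       integer(1)))
  expect_lt(abs(sum(src2$n_err) / n_alle - 0.02),
            3 * sqrt(0.02 * 0.98 / n_alle))

  # full determinism under a fixed seed
  obs2b <- simulate_observations(tr2, cfg2)
  expect_identical(obs2[c("genotype", "depth", "ref", "alt")],
                   obs2b[c("genotype", "depth", "ref", "alt")])
  expect_identical(obs2$fragments$reads, obs2b$fragments$reads)
})

test_that("truth genotypes call heterozygosity from copy counts", {
  cfg <- sim_config(n_chrom = 1, n_sites_per_chrom = 200, ploidy = 3,
                    loh_tract_rate = 0, fragment_count = 0, seed = 9)
  f <- simulate_founders(cfg)
  tr <- simulate_admixed_polyploid(f, cfg)
  g <- truth_genotype(tr)
  cc <- colSums(tr$alleles)
  expect_identical(g[cc == 0L], rep(0L, sum(cc == 0L)))
  expect_identical(g[cc == 3L], rep(2L, sum(cc == 3L)))
  expect_true(all(g[cc %in% 1:2] == 1L))
})
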