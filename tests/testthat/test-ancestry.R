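test_that("population frequencies use homozygous plus half heterozygous counts", {
  sites <- snp_sites(rep("c", 3), c(10, 20, 30))
  calls <- rbind(a = c(2L, 0L, NA), b = c(2L, 0L, NA),
                 c = c(2L, 1L, NA), d = c(2L, 1L, NA))
  gm <- genotype_matrix(calls, sites,
                        pop = c(a = "P", b = "P", c = "P", d = "P"))
  fr <- population_allele_freq(gm, "P")
  expect_equal(fr[1], 1.0)            # all homAlt
  expect_equal(fr[2], 0.25)           # 2 homRef + 2 het -> 2/8
  expect_true(is.na(fr[3]))           # all missing

  # admixed strains excluded by the 1% cap
  gm2 <- genotype_matrix(calls, sites,
                         pop = c(a = "P", b = "P", c = "P", d = "P"),
                         admixture = c(a = 0, b = 0, c = 0.5, d = 0.5))
  expect_equal(population_allele_freq(gm2, "P")[2], 0)
  expect_error(population_allele_freq(
    genotype_matrix(calls, sites, pop = c(a = "P"),
                    admixture = c(a = 0.9)), "P"), "no strains")
})

test_that("diagnostic sites require a nearly fixed difference", {
  f1 <- c(1.00, 0.98, 0.005, 0.5, NA)
  f2 <- c(0.00, 0.00, 0.995, 0.5, 0)
  tab <- select_diagnostic_sites(f1, f2)
  expect_identical(tab$site, c(1L, 3L))
  expect_identical(tab$pop1_allele, c(1L, 0L))   # alt typed pop1; ref typed pop1
  expect_identical(tab$pop2_allele, c(0L, 1L))
  # 0.98 fails the default 0.99 threshold but passes a looser one
  expect_true(2L %in% select_diagnostic_sites(f1, f2, hi = 0.95)$site)
})

test_that("diagnostic selection recovers the generator's panel exactly", {
  cfg <- sim_config(n_chrom = 2, n_sites_per_chrom = 1000,
                    frac_diagnostic = 0.3, diagnostic_leak = 0,
                    fragment_count = 0, seed = 14)
  f <- simulate_founders(cfg)
  eur <- founder_genotypes(f, "E", 30, seed = 141)
  asi <- founder_genotypes(f, "A", 30, seed = 142)
  calls <- rbind(eur, asi)
  rownames(calls) <- c(paste0("e", 1:30), paste0("a", 1:30))
  gm <- genotype_matrix(calls, f$sites,
                        pop = setNames(rep(c("E", "A"), each = 30),
                                       rownames(calls)))
  tab <- select_diagnostic_sites(population_allele_freq(gm, "E"),
                                 population_allele_freq(gm, "A"))
  # every true diagnostic site is recovered; near-fixed neutral sites may
  # occasionally join, so compare on the truth side
  expect_true(all(f$diag_sites %in% tab$site))
  expect_gt(mean(tab$site %in% f$diag_sites), 0.95)
})

test_that("group-private alleles respect both thresholds and recover ghost plants", {
  fr <- cbind(ale1 = c(0.30, 0.30, 0.00, 0.80),
              clinical = c(0.00, 0.02, 0.30, 1.00),
              wine = c(0.00, 0.00, 0.00, 1.00))
  tab <- select_group_private_alleles(fr, groups = c("ale1", "clinical"))
  expect_identical(tab$site[tab$group == "ale1"], 1L)     # 0.02 kills site 2
  expect_identical(tab$site[tab$group == "clinical"], 3L)
  # site 4: ref allele at 0.20 in ale1 -> below min_in, not selected
  expect_false(4L %in% tab$site)

  # planted ghost alleles at beer-group frequency ~0.5 are recovered
  cfg <- sim_config(n_chrom = 2, n_sites_per_chrom = 1000, ploidy = 4,
                    frac_ghost_private = 0.15, ghost_private_freq = 1,
                    ghost_lineage_frac = 0.5, loh_tract_rate = 0,
                    fragment_count = 0, seed = 15)
  f <- simulate_founders(cfg)
  beer <- t(vapply(1:12, function(i) {
    cfg_i <- sim_config(n_chrom = 2, n_sites_per_chrom = 1000, ploidy = 4,
                        frac_ghost_private = 0.15, ghost_private_freq = 1,
                        ghost_lineage_frac = 0.5, loh_tract_rate = 0,
                        fragment_count = 0, seed = 15)
    cfg_i$seed <- 500 + i
    truth_genotype(simulate_admixed_polyploid(f, cfg_i))
  }, integer(nrow(f$sites))))
  eur <- founder_genotypes(f, "E", 25, seed = 151)
  asi <- founder_genotypes(f, "A", 25, seed = 152)
  fr2 <- cbind(
    beer = colMeans(beer, na.rm = TRUE) / 2,
    eur = colMeans(eur) / 2, asi = colMeans(asi) / 2)
  tab2 <- select_group_private_alleles(fr2, groups = "beer")
  hit <- f$ghost_sites %in% tab2$site[tab2$group == "beer"]
  expect_gt(mean(hit), 0.99)
})

test_that("painting codes covered diagnostic sites and classifies purity", {
  sites <- snp_sites(rep("c", 100), seq(1000, 100000, length.out = 100))
  pan <- ancestry_panel(data.frame(site = 1:100, pop1_allele = 0L,
                                   pop2_allele = 1L))
  mk <- function(allele, idx = seq_along(allele))
    haplotype_set(list(list(id = "h", idx = idx, allele = allele,
                            support = rep(1L, length(idx)))), 100, sites)
  # all E -> E-pure at any purity
  pt <- paint(mk(rep(0L, 100)), pan, purity = 1 - 1e-9)
  expect_identical(pt$haplotypes[[1]]$class, "E-pure")
  # 96 E + 4 A -> E-pure at 0.95, mixed at 0.97
  al <- c(rep(0L, 96), rep(1L, 4))
  expect_identical(paint(mk(al), pan, 0.95)$haplotypes[[1]]$class, "E-pure")
  expect_identical(paint(mk(al), pan, 0.97)$haplotypes[[1]]$class, "mixed")
  # codes only at covered panel sites
  pt2 <- paint(mk(c(0L, 1L, 0L), idx = c(5L, 50L, 95L)), pan)
  expect_identical(pt2$haplotypes[[1]]$idx, c(5L, 50L, 95L))
  expect_identical(pt2$haplotypes[[1]]$code, c("E", "A", "E"))
})

test_that("switch counting collapses runs and honours the three filters", {
  sites <- snp_sites(rep("c", 12), seq(0, 44000, by = 4000) + 1)
  mkpt <- function(codes, pos_idx = seq_along(codes)) {
    structure(list(haplotypes = list(list(
      id = "h", idx = pos_idx, code = codes, private_idx = integer(0),
      class = "mixed", extent_bp = 0)), purity = 0.95, sites = sites,
      n_sites = 12), class = "painted_haplotypes")
  }
  expect_identical(unname(count_switches(
    mkpt(c("E", "E", "E", "A", "A", "A")))[1]), 1L)
  # middle 1-site run removed by the 5-site filter
  expect_identical(unname(count_switches(
    mkpt(c("E", "A", "E")), min_sites = 5)[1]), 0L)
  # a 2-site A run spanning 4 kb survives the 4 kb filter
  expect_identical(unname(count_switches(
    mkpt(c(rep("E", 5), "A", "A", rep("E", 5))), min_span_bp = 4000)[1]), 2L)
  # ... but a single-site run (0 bp span) does not
  expect_identical(unname(count_switches(
    mkpt(c(rep("E", 5), "A", rep("E", 6))), min_span_bp = 4000)[1]), 0L)
  # monotone under filter strengthening
  set.seed(33)
  for (i in 1:20) {
    codes <- sample(c("E", "A"), 12, replace = TRUE)
    pt <- mkpt(codes)
    s1 <- attr(count_switches(pt, 1), "total")
    s5 <- attr(count_switches(pt, 5), "total")
    s4k <- attr(count_switches(pt, min_span_bp = 4000), "total")
    expect_lte(s5, s1); expect_lte(s4k, s1)
  }
})

test_that("noiseless truth painting reproduces generator switch counts exactly", {
  cfg <- sim_config(n_chrom = 2, chrom_length = 2e5, n_sites_per_chrom = 800,
                    frac_diagnostic = 0.5, diagnostic_leak = 0,
                    frac_ghost_private = 0, loh_tract_rate = 0,
                    n_meioses = 8, admix_alpha = 0.5, ploidy = 4,
                    fragment_count = 0, seed = 5)
  f <- simulate_founders(cfg)
  tr <- simulate_admixed_polyploid(f, cfg)
  pt <- paint(truth_hapset(tr), truth_panel(f))
  got <- count_switches(pt, min_sites = 1)
  # per-(chrom, hap) painted counts aggregate to per-hap truth
  hap_of <- rep(1:4, times = 2)
  agg <- tapply(as.integer(got), hap_of, sum)
  expect_identical(unname(as.integer(agg)),
                   as.integer(truth_switches(tr, f$diag_sites)))
})

test_that("pure fractions weight haplotypes by extent", {
  sites <- snp_sites(rep("c", 100), 1:100 * 1000)
  pan <- ancestry_panel(data.frame(site = 1:100, pop1_allele = 0L,
                                   pop2_allele = 1L))
  haps <- list(
    list(id = "p", idx = 1:50, allele = rep(0L, 50),
         support = rep(1L, 50)),                       # pure E
    list(id = "m", idx = 51:100, allele = rep(c(0L, 1L), 25),
         support = rep(1L, 50)))                       # mixed
  hs <- haplotype_set(haps, 100, sites)
  pt <- paint(hs, pan)
  expect_equal(pure_fraction(pt), 0.5)
  # nMeioses = 0 truth: everything pure
  cfg <- sim_config(n_chrom = 2, n_sites_per_chrom = 300, n_meioses = 0,
                    frac_ghost_private = 0, loh_tract_rate = 0,
                    fragment_count = 0, seed = 19)
  f <- simulate_founders(cfg)
  tr <- simulate_admixed_polyploid(f, cfg)
  expect_equal(pure_fraction(paint(truth_hapset(tr), truth_panel(f))), 1.0)
})

test_that("allele copy counts use only heterozygous sites with four haplotypes", {
  sites <- snp_sites(rep("c", 6), 1:6 * 100)
  pan <- ancestry_panel(
    data.frame(site = c(1L, 2L, 3L), pop1_allele = 0L, pop2_allele = 1L),
    data.frame(site = c(4L, 5L), allele = 1L, group = "beer"))
  # four haplotypes; site 3 covered by only 3; site 6 off panel
  al <- rbind(c(1L, 1L, 1L, 1L, 0L, 0L),
              c(1L, 0L, 1L, 0L, 0L, 0L),
              c(0L, 1L, 0L, 0L, 1L, 1L),
              c(0L, 0L, NA, 0L, 0L, 1L))
  haps <- lapply(1:4, function(h) {
    idx <- which(!is.na(al[h, ]))
    list(id = paste0("h", h), idx = idx, allele = al[h, idx],
         support = rep(1L, length(idx)))
  })
  hs <- haplotype_set(haps, 6, sites)
  cc <- allele_copy_counts(hs, pan)
  expect_equal(cc$diagnostic_mean, 2)     # sites 1,2: A copies 2 and 2
  expect_equal(cc$diagnostic_n, 2L)       # site 3 excluded (3 haplotypes)
  expect_equal(cc$private_mean, 1)        # sites 4,5: 1 copy each
  # ghost alleles planted on a known number of lineages
  cfg <- sim_config(n_chrom = 1, n_sites_per_chrom = 800, ploidy = 4,
                    frac_ghost_private = 0.2, ghost_private_freq = 1,
                    ghost_lineage_frac = 0.25, loh_tract_rate = 0,
                    fragment_count = 0, seed = 23)
  f <- simulate_founders(cfg)
  tr <- simulate_admixed_polyploid(f, cfg)
  cc2 <- allele_copy_counts(truth_hapset(tr), truth_panel(f))
  expect_equal(cc2$private_mean, 1)       # exactly 1 of 4 lineages carries
})
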