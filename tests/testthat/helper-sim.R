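# shared fixture builders (everything generated in code; no data files)

# haplotype_set holding the simulator's true haplotypes, one haplotype per
# (chromosome, copy) so extents never span chromosomes
truth_hapset <- function(truth) {
  sites <- truth$sites
  np <- nrow(truth$alleles)
  haps <- list()
  for (ch in unique(sites$chrom)) {
    on <- which(sites$chrom == ch)
    for (h in seq_len(np)) {
      haps[[length(haps) + 1L]] <- list(
        id = sprintf("%s_h%d", ch, h), idx = on,
        allele = truth$alleles[h, on],
        support = rep(1L, length(on)), reads = character(0))
    }
  }
  haplotype_set(haps, nrow(sites), sites)
}

# ancestry panel from generator truth (diagnostic sites are built with the
# E pool fixed for allele 0)
truth_panel <- function(founders) {
  d <- founders$diag_sites
  diag <- data.frame(site = d, pop1_allele = rep(0L, length(d)),
                     pop2_allele = rep(1L, length(d)))
  priv <- NULL
  if (length(founders$ghost_sites))
    priv <- data.frame(site = founders$ghost_sites, allele = 1L,
                       group = "beer")
  ancestry_panel(diag, priv)
}

# random small phasing instance: k true haplotypes over s sites, n reads
# of contiguous extent, noiseless; returns the fragment set and the truth
rand_phase_instance <- function(s = sample(5:8, 1), k = sample(2:4, 1),
                                n = sample(6:12, 1)) {
  haps <- matrix(sample(0:1, k * s, replace = TRUE), k, s)
  reads <- vector("list", n)
  for (i in seq_len(n)) {
    len <- sample(2:s, 1)
    start <- sample(seq_len(s - len + 1L), 1)
    idx <- start:(start + len - 1L)
    reads[[i]] <- list(id = sprintf("r%02d", i), idx = idx,
                       allele = haps[sample(k, 1), idx])
  }
  list(fs = fragment_set(reads, s), haps = haps)
}

# switch-error proxy: fraction of adjacent covered-site pairs in each
# phased haplotype whose agree/disagree state against the best-matching
# truth haplotype flips
switch_error_rate <- function(hs, truth) {
  flips <- 0L; pairs <- 0L
  for (h in hs$haplotypes) {
    if (length(h$idx) < 2) next
    mm <- vapply(seq_len(nrow(truth$alleles)), function(k)
      sum(truth$alleles[k, h$idx] != h$allele), integer(1))
    t <- which.min(mm)
    agree <- truth$alleles[t, h$idx] == h$allele
    flips <- flips + sum(agree[-1] != agree[-length(agree)])
    pairs <- pairs + length(agree) - 1L
  }
  if (pairs == 0) return(0)
  flips / pairs
}
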