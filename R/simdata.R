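#' Configuration for the synthetic admixed-polyploid genome generator
#'
#' Defaults describe the study system being emulated: a yeast-like genome
#' with ~3 SNPs/kb, two founder populations (European-wine-like "E" and
#' Asian-sake-like "A") separated by nearly fixed diagnostic differences, a
#' third "ghost" population contributing group-private alleles, admixture
#' followed by `n_meioses` meiotic equivalents of recombination at
#' 0.34 cM/kb, polyploid genome formation, mitotic loss-of-heterozygosity
#' (LOH) tracts with 16.6 kb mean length, ~2% long-read fragment error and
#' 10-30x short-read depth.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param n_sites_per_chrom segregating SNP sites per chromosome.
#' @param n_founders_per_pop haploid founder haplotypes per population.
#' @param frac_diagnostic fraction of sites nearly fixed between E and A.
#' @param diagnostic_leak per-founder flip probability at diagnostic sites
#'   (keeps the fixed difference "nearly" fixed; < 1%).
#' @param frac_ghost_private fraction of sites carrying ghost-private alleles.
#' @param ghost_private_freq frequency of the private allele within the
#'   ghost founder pool.
#' @param n_meioses admixture age in meiotic equivalents.
#' @param cm_per_kb recombination map density, centimorgans per kb. The
#'   default 0.34 is the map figure the study's dating arithmetic uses.
#' @param admix_alpha fraction of an admixed haplotype drawn from the
#'   A (Asian-like) source; 0.40 matches the admixture proportion the
#'   f4-ratio machinery is expected to recover.
#' @param ploidy copies per admixed genome (2, 3 or 4).
#' @param ghost_lineage_frac fraction of the ploidy haplotypes carrying
#'   ghost-private alleles.
#' @param ghost_on_admixed plant ghost alleles on admixed backbones (TRUE,
#'   default) or force carrier haplotypes to a pure backbone (FALSE).
#' @param loh_tract_rate expected LOH tract initiations per kb per
#'   haplotype (a small per-position rate).
#' @param loh_tract_length_mean mean LOH tract length in bp (exponential).
#' @param fragment_count long-read fragments per simulated strain.
#' @param fragment_length_mean mean fragment length in bp (exponential).
#' @param fragment_error_rate per-allele flip probability on fragments.
#' @param short_read_depth_mean mean short-read depth per site (Poisson).
#' @param seed integer seed fixing all randomness.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 4, chrom_length = 3e5,
                       n_sites_per_chrom = 1000,
                       n_founders_per_pop = 20,
                       frac_diagnostic = 0.3, diagnostic_leak = 0.005,
                       frac_ghost_private = 0.1, ghost_private_freq = 0.5,
                       n_meioses = 10, cm_per_kb = 0.34,
                       admix_alpha = 0.4, ploidy = 4,
                       ghost_lineage_frac = 0.5, ghost_on_admixed = TRUE,
                       loh_tract_rate = 0.001, loh_tract_length_mean = 16600,
                       fragment_count = 2000, fragment_length_mean = 8000,
                       fragment_error_rate = 0.02,
                       short_read_depth_mean = 20, seed = 1) {
  cfg <- as.list(environment())
  rates <- c(frac_diagnostic, diagnostic_leak, frac_ghost_private,
             ghost_private_freq, admix_alpha, ghost_lineage_frac,
             fragment_error_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (frac_diagnostic + frac_ghost_private > 1)
    stop("frac_diagnostic + frac_ghost_private must not exceed 1")
  if (!ploidy %in% 2:4) stop("ploidy must be 2, 3 or 4")
  if (any(c(chrom_length, n_sites_per_chrom, loh_tract_length_mean,
            fragment_length_mean, cm_per_kb) <= 0))
    stop("lengths and map density must be positive")
  if (n_meioses < 0) stop("n_meioses must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate founder haplotype pools for the two source populations and the
#' ghost population
#'
#' Sites are laid down per chromosome and classified as diagnostic (E pool
#' fixed for allele 0, A pool for allele 1, up to `diagnostic_leak`),
#' ghost-private (allele 1 present only in the ghost pool, at
#' `ghost_private_freq`), or neutral (polymorphism shared by all pools at a
#' common random frequency).
#'
#' @param cfg a [sim_config].
#' @return A list of class `founder_pools`: `sites` ([snp_sites]),
#'   `site_class` ("diag"/"ghost"/"neutral"), `pools` (founder x site 0/1
#'   matrices for `E`, `A`, `G`), plus the true diagnostic and
#'   ghost-private site index sets.
#' @export
simulate_founders <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  chroms <- sprintf("chr%02d", seq_len(cfg$n_chrom))
  pos_l <- lapply(chroms, function(ch)
    sort(sample.int(cfg$chrom_length, cfg$n_sites_per_chrom)))
  sites <- snp_sites(rep(chroms, each = cfg$n_sites_per_chrom),
                     unlist(pos_l))
  ns <- nrow(sites)
  cls <- sample(c("diag", "ghost", "neutral"), ns, replace = TRUE,
                prob = c(cfg$frac_diagnostic, cfg$frac_ghost_private,
                         1 - cfg$frac_diagnostic - cfg$frac_ghost_private))
  nf <- cfg$n_founders_per_pop
  pe <- matrix(0L, nf, ns); pa <- matrix(0L, nf, ns); pg <- matrix(0L, nf, ns)

  d <- which(cls == "diag")
  if (length(d)) {
    pa[, d] <- 1L
    if (cfg$diagnostic_leak > 0) {
      flip_e <- matrix(stats::runif(nf * length(d)) < cfg$diagnostic_leak, nf)
      flip_a <- matrix(stats::runif(nf * length(d)) < cfg$diagnostic_leak, nf)
      pe[, d][flip_e] <- 1L
      pa[, d][flip_a] <- 0L
    }
    # ghost shares ancestry with both sources: fixed per site for one of
    # the two source alleles
    g_side <- stats::runif(length(d)) < 0.5
    pg[, d[g_side]] <- 1L
  }
  gp <- which(cls == "ghost")
  if (length(gp))
    pg[, gp] <- matrix(
      as.integer(stats::runif(nf * length(gp)) < cfg$ghost_private_freq), nf)
  nt <- which(cls == "neutral")
  if (length(nt)) {
    p <- stats::runif(length(nt), 0.05, 0.95)
    draw <- function() matrix(as.integer(
      stats::runif(nf * length(nt)) < rep(p, each = nf)), nf)
    pe[, nt] <- draw(); pa[, nt] <- draw(); pg[, nt] <- draw()
  }
  structure(list(sites = sites, site_class = cls,
                 diag_sites = d, ghost_sites = gp,
                 pools = list(E = pe, A = pa, G = pg), cfg = cfg),
            class = "founder_pools")
}

# junction positions and per-segment ancestry for one chromosome under the
# random-mating approximation: junctions Poisson with rate
# n_meioses * cm_per_kb / 100 per kb, ancestry redrawn iid per segment
.admixed_backbone <- function(cfg, n_meioses = cfg$n_meioses) {
  rate_bp <- n_meioses * cfg$cm_per_kb / 100 / 1000
  n_x <- stats::rpois(1, rate_bp * cfg$chrom_length)
  brk <- sort(stats::runif(n_x, 1, cfg$chrom_length))
  anc <- ifelse(stats::runif(n_x + 1) < cfg$admix_alpha, "A", "E")
  list(breaks = brk, anc = anc)
}

#' Simulate an admixed polyploid genome with LOH tracts
#'
#' Each of the `ploidy` haplotypes per chromosome is an E/A mosaic whose
#' junction density corresponds to `n_meioses` meiotic equivalents on a
#' `cm_per_kb` map; allele content within each segment is copied from a
#' random founder of the segment's population. Ghost-private alleles are
#' planted on a configurable subset of haplotypes, and mitotic LOH tracts
#' then overwrite acceptor haplotypes with donor alleles (and ancestry).
#'
#' @param founders a [simulate_founders()] result.
#' @param cfg the same [sim_config].
#' @return An object of class `truth_genome`: `alleles` and `anc`
#'   (ploidy x site matrices; ancestry codes "E", "A", "G"), `crossovers`
#'   (per chromosome, per haplotype, junction bp positions), `loh`
#'   (tract table), together with the site table and config.
#' @export
simulate_admixed_polyploid <- function(founders, cfg) {
  stopifnot(inherits(founders, "founder_pools"))
  if (!cfg$ploidy %in% 2:4) stop("ploidy must be 2, 3 or 4")
  set.seed(cfg$seed + 1L)
  sites <- founders$sites
  ns <- nrow(sites)
  np <- cfg$ploidy
  alle <- matrix(0L, np, ns)
  anc <- matrix("E", np, ns)
  chroms <- unique(sites$chrom)
  xovers <- rep(list(vector("list", np)), length(chroms))
  names(xovers) <- chroms
  nf <- cfg$n_founders_per_pop
  ghost_carrier <- seq_len(np) <= round(cfg$ghost_lineage_frac * np)

  for (ci in seq_along(chroms)) {
    on_chr <- which(sites$chrom == chroms[ci])
    pos <- sites$pos[on_chr]
    for (h in seq_len(np)) {
      pure <- cfg$n_meioses == 0 ||
        (ghost_carrier[h] && !cfg$ghost_on_admixed)
      bb <- if (pure) {
        list(breaks = numeric(0),
             anc = ifelse(stats::runif(1) < cfg$admix_alpha, "A", "E"))
      } else .admixed_backbone(cfg)
      xovers[[ci]][[h]] <- bb$breaks
      seg <- findInterval(pos, bb$breaks) + 1L
      anc[h, on_chr] <- bb$anc[seg]
      for (s in unique(seg)) {
        in_seg <- on_chr[seg == s]
        pool <- founders$pools[[bb$anc[s]]]
        alle[h, in_seg] <- pool[sample.int(nf, 1), in_seg]
      }
      if (ghost_carrier[h] && length(founders$ghost_sites)) {
        gs <- intersect(founders$ghost_sites, on_chr)
        gf <- founders$pools$G[sample.int(nf, 1), gs]
        alle[h, gs] <- gf
        anc[h, gs][gf == 1L] <- "G"
      }
    }
  }

  loh <- list()
  for (ci in seq_along(chroms)) {
    on_chr <- which(sites$chrom == chroms[ci])
    pos <- sites$pos[on_chr]
    for (h in seq_len(np)) {
      n_tr <- stats::rpois(1, cfg$loh_tract_rate * cfg$chrom_length / 1000)
      if (n_tr == 0) next
      starts <- stats::runif(n_tr, 1, cfg$chrom_length)
      lens <- stats::rexp(n_tr, 1 / cfg$loh_tract_length_mean)
      for (t in seq_len(n_tr)) {
        donor <- sample(setdiff(seq_len(np), h), 1)
        hit <- on_chr[pos >= starts[t] & pos <= starts[t] + lens[t]]
        if (length(hit)) {
          alle[h, hit] <- alle[donor, hit]
          anc[h, hit] <- anc[donor, hit]
        }
        loh[[length(loh) + 1L]] <- data.frame(
          chrom = chroms[ci], acceptor = h, donor = donor,
          start = starts[t], end = starts[t] + lens[t])
      }
    }
  }
  loh <- if (length(loh)) do.call(rbind, loh) else
    data.frame(chrom = character(0), acceptor = integer(0),
               donor = integer(0), start = numeric(0), end = numeric(0))
  structure(list(alleles = alle, anc = anc, crossovers = xovers,
                 loh = loh, sites = sites, site_class = founders$site_class,
                 cfg = cfg),
            class = "truth_genome")
}

#' @export
print.truth_genome <- function(x, ...) {
  cat("Truth genome:", nrow(x$alleles), "haplotypes x", ncol(x$alleles),
      "sites on", length(unique(x$sites$chrom)), "chromosomes\n")
  nx <- sum(lengths(unlist(x$crossovers, recursive = FALSE)))
  cat("  junctions:", nx, " LOH tracts:", nrow(x$loh), "\n")
  invisible(x)
}

#' Exact genotype of a truth genome
#'
#' The genotype call implied by the simulated haplotypes with no
#' observation noise: heterozygous iff both alleles are present among the
#' copies.
#'
#' @param truth a [truth_genome].
#' @return Integer vector of 0/1/2 codes, one per site.
#' @export
truth_genotype <- function(truth) {
  cc <- colSums(truth$alleles)
  np <- nrow(truth$alleles)
  ifelse(cc == 0L, 0L, ifelse(cc == np, 2L, 1L))
}

#' True ancestry-switch counts at a set of coded sites
#'
#' Counts, per haplotype, the number of adjacent same-chromosome site pairs
#' (restricted to `site_idx`) whose ancestry codes differ — the observable
#' crossover truth a noiseless painting must reproduce.
#'
#' @param truth a [truth_genome].
#' @param site_idx site indices to restrict to (e.g. covered diagnostic
#'   sites); default all sites.
#' @return Integer vector of switch counts, one per haplotype.
#' @export
truth_switches <- function(truth, site_idx = seq_len(ncol(truth$alleles))) {
  site_idx <- sort(site_idx)
  vapply(seq_len(nrow(truth$anc)), function(h) {
    n <- 0L
    for (ch in unique(truth$sites$chrom)) {
      j <- site_idx[truth$sites$chrom[site_idx] == ch]
      if (length(j) > 1) {
        code <- truth$anc[h, j]
        keep <- code %in% c("E", "A")
        code <- code[keep]
        if (length(code) > 1) n <- n + sum(code[-1] != code[-length(code)])
      }
    }
    n
  }, integer(1))
}

#' Simulate short-read and long-read observations of a truth genome
#'
#' Short reads: per-site depth is Poisson with mean
#' `short_read_depth_mean`, the alt count Binomial(depth, c/N) where c alt
#' copies segregate among N haplotypes; the genotype is called
#' heterozygous iff both alleles are observed, missing at depth 0.
#' Long reads: fragments sample contiguous site runs from a uniformly
#' chosen haplotype, each allele flipped with `fragment_error_rate`.
#'
#' @param truth a [truth_genome].
#' @param cfg the same [sim_config].
#' @param chrom_copies optional named vector of per-chromosome copy
#'   numbers (default: the configured ploidy everywhere); scales the
#'   expected depth by copies/ploidy to emulate aneuploidy.
#' @return A list of class `sim_observations`: `genotype` (0/1/2/NA per
#'   site), `depth`, `ref`, `alt` (per-site counts), and `fragments`
#'   (a [fragment_set] whose `source` attribute records each fragment's
#'   source haplotype and error positions).
#' @export
simulate_observations <- function(truth, cfg, chrom_copies = NULL) {
  set.seed(cfg$seed + 2L)
  sites <- truth$sites
  ns <- nrow(sites)
  np <- nrow(truth$alleles)
  cc <- colSums(truth$alleles)

  mult <- rep(1, ns)
  if (!is.null(chrom_copies)) {
    m <- chrom_copies[sites$chrom] / np
    mult[!is.na(m)] <- m[!is.na(m)]
  }
  depth <- stats::rpois(ns, cfg$short_read_depth_mean * mult)
  alt <- stats::rbinom(ns, depth, cc / np)
  ref <- depth - alt
  geno <- rep(NA_integer_, ns)
  geno[depth > 0 & alt == 0L] <- 0L
  geno[depth > 0 & alt == depth] <- 2L
  geno[alt > 0L & ref > 0L] <- 1L

  chroms <- unique(sites$chrom)
  reads <- vector("list", cfg$fragment_count)
  src <- data.frame(id = character(cfg$fragment_count),
                    chrom = character(cfg$fragment_count),
                    hap = integer(cfg$fragment_count),
                    n_err = integer(cfg$fragment_count))
  kept <- logical(cfg$fragment_count)
  for (i in seq_len(cfg$fragment_count)) {
    ch <- chroms[sample.int(length(chroms), 1)]
    on_chr <- which(sites$chrom == ch)
    start <- stats::runif(1, 1, cfg$chrom_length)
    len <- stats::rexp(1, 1 / cfg$fragment_length_mean)
    idx <- on_chr[sites$pos[on_chr] >= start &
                    sites$pos[on_chr] <= start + len]
    if (length(idx) < 2L) next
    h <- sample.int(np, 1)
    a <- truth$alleles[h, idx]
    err <- stats::runif(length(a)) < cfg$fragment_error_rate
    a[err] <- 1L - a[err]
    id <- sprintf("frag%05d", i)
    reads[[i]] <- list(id = id, idx = idx, allele = as.integer(a))
    src$id[i] <- id; src$chrom[i] <- ch
    src$hap[i] <- h; src$n_err[i] <- sum(err)
    kept[i] <- TRUE
  }
  fs <- fragment_set(reads[kept], ns)
  attr(fs, "source") <- src[kept, , drop = FALSE]
  structure(list(genotype = geno, depth = depth, ref = ref, alt = alt,
                 fragments = fs, sites = sites),
            class = "sim_observations")
}

#' Sample diploid strains directly from a founder pool
#'
#' Convenience for building reference-population genotype rows: each
#' strain is the union of two founder haplotypes drawn (with replacement)
#' from one pool, optionally after a generation of binomial drift of the
#' pool frequencies.
#'
#' @param founders a [simulate_founders()] result.
#' @param pop "E", "A" or "G".
#' @param n number of strains.
#' @param drift optional integer: when > 0, strains are drawn from a
#'   drifted copy of the pool obtained by resampling `drift` founders with
#'   replacement (an independently evolved related population).
#' @param seed seed for this draw.
#' @return Integer matrix, strains x sites, genotype codes 0/1/2.
#' @export
founder_genotypes <- function(founders, pop, n, drift = 0, seed = 1) {
  set.seed(seed)
  pool <- founders$pools[[pop]]
  if (drift > 0)
    pool <- pool[sample.int(nrow(pool), drift, replace = TRUE), , drop = FALSE]
  t(vapply(seq_len(n), function(i) {
    h1 <- pool[sample.int(nrow(pool), 1), ]
    h2 <- pool[sample.int(nrow(pool), 1), ]
    as.integer(h1 + h2)
  }, integer(ncol(pool))))
}
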