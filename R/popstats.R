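#' f4 statistic from four population allele-frequency vectors
#'
#' The mean over shared sites of (pA - pB)(pC - pD); sites missing a
#' frequency in any population are dropped. Nonzero values indicate
#' population-tree discordance caused by admixture.
#'
#' @param pa,pb,pc,pd per-site alternate-allele frequencies.
#' @return The f4 value.
#' @export
f4 <- function(pa, pb, pc, pd) {
  stopifnot(length(pa) == length(pb), length(pa) == length(pc),
            length(pa) == length(pd))
  ok <- !(is.na(pa) | is.na(pb) | is.na(pc) | is.na(pd))
  if (!any(ok)) stop("no sites shared by all four populations")
  mean((pa[ok] - pb[ok]) * (pc[ok] - pd[ok]))
}

# frequency vector for a "population" spec: a population label, a strain
# name (its own dosage/2), a character vector of strains, or a numeric
# frequency vector
.freq_of <- function(gm, spec, max_admixture) {
  if (is.numeric(spec)) return(spec)
  if (length(spec) == 1 && spec %in% gm$strains &&
      !(!is.null(gm$pop) && spec %in% gm$pop)) {
    return(gm$calls[spec, ] / 2)
  }
  population_allele_freq(gm, spec, max_admixture = max_admixture)
}

#' f4 with block-jackknife standard error
#'
#' Computes f4 over the complete-case sites and a delete-one-block
#' jackknife over consecutive blocks of `block_size` SNPs in genome order
#' (the final partial block is merged into the previous one):
#' se^2 = ((B - 1)/B) * sum((theta_-i - mean(theta_-i))^2), Z = value/se.
#'
#' @param gm a [genotype_matrix] with population labels.
#' @param pops length-4 specification (population labels, strain names or
#'   numeric frequency vectors) for A, B, C, D.
#' @param block_size SNPs per jackknife block (default 500).
#' @param max_admixture admixture cap passed to
#'   [population_allele_freq()] (default 0.01).
#' @return An object of class `f4_result`: `value`, `se`, `z`,
#'   `n_blocks`, `block_size`, `n_sites`.
#' @export
f4_jackknife <- function(gm, pops, block_size = 500, max_admixture = 0.01) {
  stopifnot(length(pops) == 4)
  fr <- lapply(pops, .freq_of, gm = gm, max_admixture = max_admixture)
  ok <- !Reduce(`|`, lapply(fr, is.na))
  d <- (fr[[1]][ok] - fr[[2]][ok]) * (fr[[3]][ok] - fr[[4]][ok])
  n <- length(d)
  value <- mean(d)
  n_blocks <- n %/% block_size
  if (n_blocks < 2) {
    return(structure(list(value = value, se = NA_real_, z = NA_real_,
                          n_blocks = n_blocks, block_size = block_size,
                          n_sites = n),
                     class = "f4_result"))
  }
  blk <- pmin(ceiling(seq_len(n) / block_size), n_blocks)  # merge remainder
  tot <- sum(d)
  bsum <- rowsum(d, blk)[, 1]
  bn <- tabulate(blk, n_blocks)
  theta <- (tot - bsum) / (n - bn)
  se <- sqrt((n_blocks - 1) / n_blocks * sum((theta - mean(theta))^2))
  z <- if (se > 0) value / se else NA_real_
  structure(list(value = value, se = se, z = z, n_blocks = n_blocks,
                 block_size = block_size, n_sites = n),
            class = "f4_result")
}

#' @export
print.f4_result <- function(x, ...) {
  cat("f4 =", signif(x$value, 5), " se =", signif(x$se, 4),
      " Z =", round(x$z, 2), "\n")
  cat("  ", x$n_sites, "sites in", x$n_blocks, "blocks of",
      x$block_size, "\n")
  invisible(x)
}

#' f4-ratio admixture proportion
#'
#' alpha = f4(R1, R2; test, S2) / f4(R1, R2; S1, S2), the fraction of the
#' test genome derived from source S1 (e.g. the Asian-like source when S2
#' is the European-like source). A single test strain is used with its
#' own genotype dosage as a one-sample frequency. The value is reported
#' raw (it may fall slightly outside [0, 1]); a weak-denominator flag is
#' raised when |denominator Z| < 3.
#'
#' @param gm a [genotype_matrix] with population labels.
#' @param ref_pops length-2 reference population spec (R1, R2).
#' @param source_pops length-2 source spec (S1, S2).
#' @param test test population, strain name, or frequency vector.
#' @param block_size jackknife block size (default 500).
#' @param max_admixture admixture cap for panel populations.
#' @return An object of class `admixture_proportion`: `alpha`, `num`,
#'   `den` ([f4_jackknife()] results), `weak_denominator`.
#' @export
f4_admixture_proportion <- function(gm, ref_pops, source_pops, test,
                                    block_size = 500, max_admixture = 0.01) {
  stopifnot(length(ref_pops) == 2, length(source_pops) == 2)
  num <- f4_jackknife(gm, list(ref_pops[[1]], ref_pops[[2]],
                               test, source_pops[[2]]),
                      block_size, max_admixture)
  den <- f4_jackknife(gm, list(ref_pops[[1]], ref_pops[[2]],
                               source_pops[[1]], source_pops[[2]]),
                      block_size, max_admixture)
  if (abs(den$value) < 1e-12) {
    alpha <- NA_real_
    warning("f4 denominator numerically zero; alpha undefined")
  } else alpha <- num$value / den$value
  structure(list(alpha = alpha, num = num, den = den,
                 weak_denominator = is.na(den$z) || abs(den$z) < 3),
            class = "admixture_proportion")
}

#' @export
print.admixture_proportion <- function(x, ...) {
  cat("f4-ratio admixture proportion alpha =", round(x$alpha, 4), "\n")
  cat("  numerator f4 =", signif(x$num$value, 4),
      " denominator f4 =", signif(x$den$value, 4),
      if (x$weak_denominator) " [weak denominator]" else "", "\n")
  invisible(x)
}

#' Lineage divergence from a private-allele count
#'
#' @param n_alleles number of lineage-private alleles observed.
#' @param n_sites number of (e.g. four-fold degenerate) sites surveyed.
#' @return Divergence in percent: 100 * n_alleles / n_sites.
#' @export
lineage_divergence <- function(n_alleles, n_sites) {
  if (any(n_sites <= 0)) stop("n_sites must be positive")
  if (any(n_alleles < 0)) stop("n_alleles must be non-negative")
  100 * n_alleles / n_sites
}

#' Molecular-clock divergence time
#'
#' years = (divergence/100) / (mu * generations_per_year).
#'
#' @param divergence_percent lineage divergence in percent.
#' @param mu per-base mutation rate per generation (default 5e-10).
#' @param gen_per_year generations per year (default 150, a brewing-strain
#'   figure).
#' @return Age in years.
#' @export
divergence_time <- function(divergence_percent, mu = 5e-10,
                            gen_per_year = 150) {
  if (any(c(divergence_percent, mu, gen_per_year) <= 0))
    stop("all inputs must be positive")
  (divergence_percent / 100) / (mu * gen_per_year)
}

#' Expected mitotic gene-conversion and recombination events per division
#'
#' Scales published per-division rates to a genome of `genome_kb`:
#' conversions = conv_rate * genome_kb / track_kb, recombinations =
#' rec_rate * genome_kb / rec_window_kb. Defaults describe a tetraploid
#' yeast genome of ~48 Mbp with a 16.6 kb median conversion track and a
#' recombination rate quoted per 120 kb.
#'
#' @param genome_kb genome size in kb (default 48000).
#' @param conv_rate gene-conversion rate per cell division (default 1.3e-6).
#' @param track_kb median conversion track length in kb (default 16.6).
#' @param rec_rate recombination rate per cell division per window
#'   (default 7e-6).
#' @param rec_window_kb window the recombination rate is quoted per
#'   (default 120).
#' @return A list with `conversions` and `recombinations` per division.
#' @export
expected_mitotic_events <- function(genome_kb = 48000, conv_rate = 1.3e-6,
                                    track_kb = 16.6, rec_rate = 7e-6,
                                    rec_window_kb = 120) {
  if (any(c(genome_kb, conv_rate, track_kb, rec_rate, rec_window_kb) <= 0))
    stop("all inputs must be positive")
  list(conversions = conv_rate * genome_kb / track_kb,
       recombinations = rec_rate * genome_kb / rec_window_kb)
}

#' Genotype discordance between two call vectors
#'
#' @param calls1,calls2 genotype code vectors (0/1/2/NA) over the same
#'   sites, e.g. two independently sequenced replicates of one strain.
#' @return Fraction of discordant calls among sites called in both.
#' @export
genotype_discordance <- function(calls1, calls2) {
  stopifnot(length(calls1) == length(calls2))
  ok <- !is.na(calls1) & !is.na(calls2)
  if (!any(ok)) stop("no sites called in both strains")
  mean(calls1[ok] != calls2[ok])
}
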