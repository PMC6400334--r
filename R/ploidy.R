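#' Classify strain ploidy from allele balance at heterozygous sites
#'
#' The alternate-allele read fraction at heterozygous sites concentrates
#' around 1/2 for diploids, {1/3, 2/3} for triploids and {1/4, 1/2, 3/4}
#' for tetraploids. Each class is scored as a fixed-weight binomial
#' mixture (equal component weights) and the maximum-likelihood class is
#' returned. Sites below `min_depth`, or with alt fraction outside
#' [0.05, 0.95] (a sequencing-error floor for miscalled heterozygotes),
#' are excluded. With fewer than `min_het` usable sites the call is
#' `unknown`, unless the data decisively reject the diploid model
#' (log-likelihood margin > log(100)), in which case
#' `polyploid-unresolved` is returned.
#'
#' @param ref,alt integer vectors of reference/alternate read counts at
#'   the strain's heterozygous sites.
#' @param min_depth minimum per-site depth (default 10).
#' @param min_het minimum usable heterozygous sites for a resolved call
#'   (default 500).
#' @param strain optional strain name carried into the result.
#' @return An object of class `ploidy_call` with fields `strain`,
#'   `ploidy` (`"2"`, `"3"`, `"4"`, `"polyploid-unresolved"` or
#'   `"unknown"`), `n_het_used`, `mean_depth` and per-class
#'   log-likelihoods in `scores`.
#' @export
call_ploidy <- function(ref, alt, min_depth = 10, min_het = 500,
                        strain = NA_character_) {
  stopifnot(length(ref) == length(alt))
  depth <- ref + alt
  f <- ifelse(depth > 0, alt / depth, NA_real_)
  use <- which(depth >= min_depth & !is.na(f) & f >= 0.05 & f <= 0.95)
  n_used <- length(use)
  mean_depth <- if (length(depth)) mean(depth) else NA_real_
  comp <- list("2" = 1 / 2, "3" = c(1 / 3, 2 / 3),
               "4" = c(1 / 4, 1 / 2, 3 / 4))
  if (n_used == 0) {
    return(structure(list(strain = strain, ploidy = "unknown",
                          n_het_used = 0L, mean_depth = mean_depth,
                          scores = c("2" = NA_real_, "3" = NA_real_,
                                     "4" = NA_real_)),
                     class = "ploidy_call"))
  }
  a <- alt[use]; n <- depth[use]
  scores <- vapply(comp, function(p) {
    w <- rep(1 / length(p), length(p))
    lik <- rowSums(vapply(seq_along(p), function(j)
      w[j] * stats::dbinom(a, n, p[j]), numeric(length(a))))
    sum(log(pmax(lik, .Machine$double.xmin)))
  }, numeric(1))
  best <- names(scores)[which.max(scores)]   # which.max: first = lowest ploidy
  ploidy <- if (n_used >= min_het) best
  else if (best != "2" && scores[best] - scores["2"] > log(100))
    "polyploid-unresolved"
  else "unknown"
  structure(list(strain = strain, ploidy = ploidy, n_het_used = n_used,
                 mean_depth = mean_depth, scores = scores),
            class = "ploidy_call")
}

#' @export
print.ploidy_call <- function(x, ...) {
  cat("Ploidy call", if (!is.na(x$strain)) paste0("(", x$strain, ")"),
      ": ", x$ploidy, "\n", sep = "")
  cat("  het sites used:", x$n_het_used,
      " mean depth:", round(x$mean_depth, 1), "\n")
  if (!all(is.na(x$scores))) {
    rel <- x$scores - max(x$scores, na.rm = TRUE)
    cat("  log-likelihood (relative):",
        paste(names(rel), round(rel, 1), sep = "n=", collapse = "  "), "\n")
  }
  invisible(x)
}

#' Call ploidy for every strain of a genotype matrix
#'
#' Applies [call_ploidy()] to each strain's read counts at its
#' heterozygous-called sites.
#'
#' @param gm a [genotype_matrix].
#' @param counts the matching [site_read_counts].
#' @inheritParams call_ploidy
#' @return A data.frame with one row per strain: `strain`, `ploidy`,
#'   `n_het_used`, `mean_depth`.
#' @export
call_ploidy_all <- function(gm, counts, min_depth = 10, min_het = 500) {
  rows <- lapply(gm$strains, function(s) {
    i <- match(s, gm$strains)
    het <- which(gm$calls[i, ] == 1L)
    pc <- call_ploidy(counts$ref[i, het], counts$alt[i, het],
                      min_depth = min_depth, min_het = min_het, strain = s)
    data.frame(strain = s, ploidy = pc$ploidy,
               n_het_used = pc$n_het_used, mean_depth = pc$mean_depth)
  })
  do.call(rbind, rows)
}

#' Flag chromosome-level aneuploidy from relative coverage
#'
#' Each chromosome's median depth is divided by the genome-wide median of
#' chromosome medians; chromosomes whose ratio deviates from 1 by more
#' than `threshold` are flagged.
#'
#' @param depth per-site read depth vector.
#' @param sites the matching [snp_sites] table.
#' @param threshold flag when `|ratio - 1| > threshold` (default 0.20).
#' @return A data.frame `chrom`, `median_depth`, `ratio`, `flagged`.
#' @export
detect_aneuploidy <- function(depth, sites, threshold = 0.20) {
  stopifnot(length(depth) == nrow(sites))
  chroms <- unique(sites$chrom)
  if (length(chroms) < 2)
    stop("aneuploidy is not assessable with a single chromosome")
  med <- vapply(chroms, function(ch)
    stats::median(depth[sites$chrom == ch]), numeric(1))
  ratio <- med / stats::median(med)
  data.frame(chrom = chroms, median_depth = med, ratio = ratio,
             flagged = abs(ratio - 1) > threshold, row.names = NULL)
}
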