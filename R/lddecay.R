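#' Ancestry covariance versus distance on painted haplotypes
#'
#' Ancestry codes are scored E = 0, A = 1 and mean-centered per site
#' across the haplotypes covering it; invariant sites are excluded. For
#' every within-haplotype pair of coded sites on the same chromosome with
#' separation between `min_dist` and `max_dist`, the product of centered
#' codes is accumulated and binned by distance.
#'
#' @param painted a [paint()] result (needs site coordinates).
#' @param min_dist,max_dist distance window in bp (defaults 1000, 50000).
#' @param bin bin width in bp (default 100).
#' @return A data.frame of class `decay_curve`: `mid` (bin midpoint, bp),
#'   `mean_cov`, `n_pairs`; empty-bin rows are dropped.
#' @export
ancestry_covariance <- function(painted, min_dist = 1000, max_dist = 50000,
                                bin = 100) {
  if (is.null(painted$sites))
    stop("painted haplotypes carry no site coordinates")
  sites <- painted$sites
  n <- painted$n_sites
  haps <- painted$haplotypes
  H <- matrix(NA_real_, length(haps), n)
  for (k in seq_along(haps)) {
    h <- haps[[k]]
    if (length(h$idx)) H[k, h$idx] <- as.numeric(h$code == "A")
  }
  covd <- colSums(!is.na(H))
  mu <- colMeans(H, na.rm = TRUE)
  variant <- covd > 0 & mu > 0 & mu < 1        # invariant sites excluded
  if (sum(variant) < 2) {
    out <- data.frame(mid = numeric(0), mean_cov = numeric(0),
                      n_pairs = integer(0))
    class(out) <- c("decay_curve", "data.frame")
    return(out)
  }
  C <- sweep(H, 2, mu, "-")
  C[is.na(C)] <- 0
  V <- matrix(as.numeric(!is.na(H)), nrow(H))
  C[, !variant] <- 0
  V[, !variant] <- 0

  n_bins <- ceiling((max_dist - min_dist) / bin)
  sum_b <- numeric(n_bins); cnt_b <- numeric(n_bins)
  for (ch in unique(sites$chrom)) {
    j <- which(sites$chrom == ch & variant)
    if (length(j) < 2) next
    P <- crossprod(C[, j, drop = FALSE])      # sum over haps of products
    N <- crossprod(V[, j, drop = FALSE])      # contributing hap counts
    d <- abs(outer(sites$pos[j], sites$pos[j], "-"))
    sel <- upper.tri(d) & d >= min_dist & d <= max_dist & N > 0
    if (!any(sel)) next
    b <- pmin(floor((d[sel] - min_dist) / bin) + 1L, n_bins)
    acc <- rowsum(cbind(P[sel], N[sel]), group = b)
    at <- as.integer(rownames(acc))
    sum_b[at] <- sum_b[at] + acc[, 1]
    cnt_b[at] <- cnt_b[at] + acc[, 2]
  }
  keep <- cnt_b > 0
  out <- data.frame(mid = min_dist + (seq_len(n_bins) - 0.5) * bin,
                    mean_cov = ifelse(keep, sum_b / cnt_b, NA_real_),
                    n_pairs = cnt_b)[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("decay_curve", "data.frame")
  out
}

#' Fit an exponential decay to an ancestry-covariance curve
#'
#' Least-squares fit of `cov(x) = amplitude * exp(-x / d)` weighted by the
#' number of site pairs per bin. The half-distance is `d * ln 2`, and the
#' decay scale is converted to meiotic equivalents with
#' [meiotic_equivalents()].
#'
#' @param curve a [ancestry_covariance()] result with >= 10 non-empty bins.
#' @param cm_per_kb map density used for the meiotic conversion
#'   (default 0.34).
#' @return An object of class `decay_fit`: `amplitude`, `scale_bp`,
#'   `half_distance_bp`, `meiotic_equivalents`, `converged`, `no_decay`,
#'   and the fitted model.
#' @export
fit_decay <- function(curve, cm_per_kb = 0.34) {
  curve <- curve[!is.na(curve$mean_cov) & curve$n_pairs > 0, , drop = FALSE]
  if (nrow(curve) < 10) stop("need at least 10 non-empty bins to fit")
  if (all(curve$mean_cov == 0)) {
    return(structure(list(amplitude = NA_real_, scale_bp = NA_real_,
                          half_distance_bp = NA_real_,
                          meiotic_equivalents = NA_real_,
                          converged = FALSE, no_decay = FALSE,
                          model = NULL, curve = curve),
                     class = "decay_fit"))
  }
  d_max <- 20 * max(curve$mid)
  # log-linear start values from the positive bins
  pos <- curve$mean_cov > 0
  start <- if (sum(pos) >= 2) {
    lf <- stats::lm(log(mean_cov) ~ mid, data = curve[pos, ],
                    weights = curve$n_pairs[pos])
    sl <- unname(stats::coef(lf)[2])
    list(A = exp(unname(stats::coef(lf)[1])),
         d = if (sl < 0) min(-1 / sl, d_max) else d_max)
  } else list(A = max(curve$mean_cov), d = d_max)
  fit <- tryCatch(
    minpack.lm::nlsLM(mean_cov ~ A * exp(-mid / d), data = curve,
                      start = start, weights = curve$n_pairs,
                      lower = c(A = 0, d = 1),
                      upper = c(A = Inf, d = d_max),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(amplitude = NA_real_, scale_bp = NA_real_,
                          half_distance_bp = NA_real_,
                          meiotic_equivalents = NA_real_,
                          converged = FALSE, no_decay = FALSE,
                          model = NULL, curve = curve),
                     class = "decay_fit"))
  }
  cf <- stats::coef(fit)
  # a scale pinned at the optimiser's upper bound means no measurable decay
  no_decay <- cf["d"] >= 0.95 * d_max
  structure(list(amplitude = unname(cf["A"]), scale_bp = unname(cf["d"]),
                 half_distance_bp = unname(cf["d"]) * log(2),
                 meiotic_equivalents = if (no_decay) NA_real_ else
                   meiotic_equivalents(unname(cf["d"]) / 1000, cm_per_kb),
                 converged = TRUE, no_decay = no_decay,
                 model = fit, curve = curve),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (!x$converged) { cat("Decay fit: not converged\n"); return(invisible(x)) }
  cat("Exponential ancestry-LD decay fit\n")
  cat("  amplitude:", signif(x$amplitude, 4),
      " scale:", round(x$scale_bp), "bp",
      " half-distance:", round(x$half_distance_bp), "bp\n")
  if (x$no_decay) cat("  no decay over the fitted window\n")
  else cat("  meiotic equivalents:", round(x$meiotic_equivalents, 1), "\n")
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) {
  c(amplitude = object$amplitude, scale_bp = object$scale_bp)
}

#' @export
predict.decay_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$curve$mid else newdata$mid
  object$amplitude * exp(-x / object$scale_bp)
}

#' @export
plot.decay_fit <- function(x, ...) {
  plot(x$curve$mid / 1000, x$curve$mean_cov, xlab = "distance (kb)",
       ylab = "mean ancestry covariance", pch = 16, cex = 0.5, ...)
  if (x$converged)
    graphics::curve(x$amplitude * exp(-(1000 * z) / x$scale_bp),
                    xname = "z", add = TRUE, col = 2)
  invisible(x)
}

#' Convert an LD-decay distance to meiotic equivalents
#'
#' The decay scale of admixture LD shrinks with the number of meioses
#' since admixture: t = 100 / (d_kb * cm_per_kb). With the default map
#' density this reproduces the study arithmetic (30 kb -> 9.8 meioses;
#' 6.3 kb -> 46.7).
#'
#' @param decay_kb decay scale in kb (> 0).
#' @param cm_per_kb map density in cM per kb (default 0.34; see the
#'   methods vignette for the unit discussion).
#' @return Meiotic equivalents since admixture.
#' @export
meiotic_equivalents <- function(decay_kb, cm_per_kb = 0.34) {
  if (any(decay_kb <= 0)) stop("decay distance must be positive")
  100 / (decay_kb * cm_per_kb)
}
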