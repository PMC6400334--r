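#' Merge parameters for the greedy ploidy-agnostic phaser
#'
#' @param min_overlap minimum number of shared SNPs for a join (default 4).
#' @param min_match_frac minimum fraction of matching SNPs over the
#'   overlap for rounds after the first (default 0.80).
#' @param mismatch_penalty weight of a mismatch in the join score
#'   `matches - penalty * mismatches` (default 5).
#' @param rounds merge rounds; the first admits only mismatch-free joins,
#'   later rounds use the match-fraction criterion (default 3).
#' @return A list of class `merge_params`.
#' @export
merge_params <- function(min_overlap = 4, min_match_frac = 0.80,
                         mismatch_penalty = 5, rounds = 3) {
  if (min_overlap < 1) stop("min_overlap must be >= 1")
  if (min_match_frac <= 0 || min_match_frac > 1)
    stop("min_match_frac must be in (0, 1]")
  structure(list(min_overlap = as.integer(min_overlap),
                 min_match_frac = min_match_frac,
                 mismatch_penalty = mismatch_penalty,
                 rounds = as.integer(rounds)),
            class = "merge_params")
}

#' Score the overlap of two sparse allele vectors
#'
#' Matches and mismatches are counted over the sites keyed in both
#' vectors; the join score is `matches - penalty * mismatches`.
#'
#' @param a,b named or index-aligned allele representations: either lists
#'   with `idx`/`allele` components or plain integer vectors with `NA` at
#'   uncovered sites.
#' @param mismatch_penalty penalty per mismatch (default 5).
#' @return A list with `matches`, `mismatches`, `score`. A zero-site
#'   overlap scores (0, 0, 0).
#' @export
score_overlap <- function(a, b, mismatch_penalty = 5) {
  av <- if (is.list(a)) .sparse_pair(a, b) else list(a = a, b = b)
  sh <- which(!is.na(av$a) & !is.na(av$b))
  m <- sum(av$a[sh] == av$b[sh])
  x <- length(sh) - m
  list(matches = m, mismatches = x, score = m - mismatch_penalty * x)
}

.sparse_pair <- function(a, b) {
  n <- max(c(a$idx, b$idx, 0L))
  va <- rep(NA_integer_, n); va[a$idx] <- a$allele
  vb <- rep(NA_integer_, n); vb[b$idx] <- b$allele
  list(a = va, b = vb)
}

# Greedy merging engine. Items (reads, later haplotypes) carry per-site
# 0/1 support counts; the consensus is the majority allele, ties resolved
# at merge time in favour of the component with more per-site support,
# then more member reads, then the earlier canonical rank.
.phase_engine <- function(reads, n_sites, params) {
  n <- length(reads)
  n0 <- matrix(0L, n, n_sites)
  n1 <- matrix(0L, n, n_sites)
  cons <- matrix(NA_integer_, n, n_sites)
  for (i in seq_len(n)) {
    r <- reads[[i]]
    n1[i, r$idx] <- r$allele
    n0[i, r$idx] <- 1L - r$allele
    cons[i, r$idx] <- r$allele
  }
  nreads <- rep(1L, n)
  members <- lapply(reads, function(r) r$id)
  active <- rep(TRUE, n)
  # 0/1 indicator matrices of the consensus, for vectorised pair scoring
  A1 <- matrix(0, n, n_sites); A1[which(cons == 1L)] <- 1
  A0 <- matrix(0, n, n_sites); A0[which(cons == 0L)] <- 1

  M <- A1 %*% t(A1) + A0 %*% t(A0)   # matches
  X <- A1 %*% t(A0) + A0 %*% t(A1)   # mismatches
  diag(M) <- 0; diag(X) <- 0

  pen <- params$mismatch_penalty

  best_of_row <- function(i, strict) {
    m <- M[i, ]; x <- X[i, ]
    ov <- m + x
    elig <- active & ov >= params$min_overlap
    elig[i] <- FALSE
    if (strict) elig <- elig & x == 0
    else elig <- elig & (m / pmax(ov, 1)) >= params$min_match_frac
    s <- m - pen * x
    elig <- elig & s > 0
    if (!any(elig)) return(c(-Inf, NA, 0))
    s[!elig] <- -Inf
    j <- which(s == max(s))
    if (length(j) > 1) {          # more matches, then lower rank
      j <- j[m[j] == max(m[j])]
      j <- j[1]
    }
    c(s[j], j, m[j])
  }

  run_round <- function(strict) {
    rb_score <- rep(-Inf, n); rb_j <- rep(NA_integer_, n); rb_m <- rep(0, n)
    for (i in which(active)) {
      b <- best_of_row(i, strict)
      rb_score[i] <- b[1]; rb_j[i] <- b[2]; rb_m[i] <- b[3]
    }
    repeat {
      cand <- which(active & is.finite(rb_score))
      if (!length(cand)) break
      sm <- max(rb_score[cand])
      i <- cand[rb_score[cand] == sm]
      if (length(i) > 1) i <- i[which.max(rb_m[i])]
      i <- i[1]
      j <- rb_j[i]
      if (j < i) { tmp <- i; i <- j; j <- tmp }   # keep lower rank

      # merge j into i
      ti0 <- n0[i, ]; ti1 <- n1[i, ]
      n0[i, ] <<- ti0 + n0[j, ]
      n1[i, ] <<- ti1 + n1[j, ]
      new_cons <- ifelse(n1[i, ] > n0[i, ], 1L,
                         ifelse(n0[i, ] > n1[i, ], 0L, NA_integer_))
      tie <- which(is.na(new_cons) & (n0[i, ] + n1[i, ]) > 0L)
      if (length(tie)) {
        si <- pmax(ti0[tie], ti1[tie])
        sj <- pmax(n0[j, tie], n1[j, tie])
        from_i <- si > sj |
          (si == sj & (nreads[i] > nreads[j] | nreads[i] == nreads[j]))
        new_cons[tie] <- ifelse(from_i, cons[i, tie], cons[j, tie])
      }
      cons[i, ] <<- new_cons
      nreads[i] <<- nreads[i] + nreads[j]
      members[[i]] <<- c(members[[i]], members[[j]])
      active[j] <<- FALSE
      A1[i, ] <<- as.numeric(!is.na(new_cons) & new_cons == 1L)
      A0[i, ] <<- as.numeric(!is.na(new_cons) & new_cons == 0L)
      A1[j, ] <<- 0; A0[j, ] <<- 0
      mi <- A1 %*% A1[i, ] + A0 %*% A0[i, ]
      xi <- A1 %*% A0[i, ] + A0 %*% A1[i, ]
      M[i, ] <<- mi; M[, i] <<- mi
      X[i, ] <<- xi; X[, i] <<- xi
      M[i, i] <<- 0; X[i, i] <<- 0
      rb_score[j] <- -Inf
      stale <- unique(c(i, which(active & (rb_j == i | rb_j == j))))
      # rows whose cached best might now be beaten by the new item i
      bi <- best_of_row(i, strict)
      rb_score[i] <- bi[1]; rb_j[i] <- bi[2]; rb_m[i] <- bi[3]
      for (k in setdiff(stale, i)) {
        b <- best_of_row(k, strict)
        rb_score[k] <- b[1]; rb_j[k] <- b[2]; rb_m[k] <- b[3]
      }
      if (is.finite(rb_score[i])) {
        # i may have become the best partner for other rows
        mrow <- M[, i]; xrow <- X[, i]
        ov <- mrow + xrow
        elig <- active & ov >= params$min_overlap
        elig[i] <- FALSE
        if (strict) elig <- elig & xrow == 0
        else elig <- elig & (mrow / pmax(ov, 1)) >= params$min_match_frac
        s <- mrow - pen * xrow
        upd <- which(elig & s > 0 & s >= rb_score)
        for (k in setdiff(upd, i)) {
          b <- best_of_row(k, strict)
          rb_score[k] <- b[1]; rb_j[k] <- b[2]; rb_m[k] <- b[3]
        }
      }
    }
  }

  environment(run_round) <- environment()
  run_round(strict = TRUE)
  for (r in seq_len(max(params$rounds - 1L, 0L))) run_round(strict = FALSE)

  list(n0 = n0, n1 = n1, cons = cons, members = members,
       active = active, nreads = nreads)
}

#' Phase long-read fragments into a variable number of haplotypes
#'
#' Greedy iterative merging of reads into haplotypes with no prior on
#' ploidy. Reads are first canonically sorted (extent start, length
#' descending, id). In round one, reads join only with zero mismatches
#' over an overlap of at least `min_overlap` SNPs; in later rounds,
#' haplotypes (and still-unplaced reads) merge when the overlap has at
#' least `min_match_frac` matching SNPs. The globally best-scoring
#' eligible pair (score = matches - penalty x mismatches, required > 0) is
#' merged first and scores are refreshed after every merge. The consensus
#' at conflicting sites is the majority of supporting reads. Haplotypes
#' covering fewer than `min_overlap` sites are dropped from the output.
#'
#' @param fs a [fragment_set].
#' @param params a [merge_params].
#' @param sites optional [snp_sites] table attached to the result.
#' @return A [haplotype_set]; haplotypes are ordered by extent start and
#'   carry the ids of their member reads.
#' @export
phase <- function(fs, params = merge_params(), sites = NULL) {
  if (!length(fs$reads))
    return(haplotype_set(list(), fs$n_sites, sites))
  starts <- vapply(fs$reads, function(r) r$idx[1], integer(1))
  lens <- vapply(fs$reads, function(r) length(r$idx), integer(1))
  ids <- vapply(fs$reads, `[[`, character(1), "id")
  o <- order(starts, -lens, ids)
  reads <- fs$reads[o]

  st <- .phase_engine(reads, fs$n_sites, params)

  keep <- which(st$active)
  cov_n <- vapply(keep, function(i) sum(!is.na(st$cons[i, ])), integer(1))
  ok <- cov_n >= params$min_overlap
  keep <- keep[ok]; cov_n <- cov_n[ok]
  if (!length(keep)) return(haplotype_set(list(), fs$n_sites, sites))
  first <- vapply(keep, function(i) which(!is.na(st$cons[i, ]))[1], integer(1))
  keep <- keep[order(first, -cov_n)]
  haps <- lapply(seq_along(keep), function(k) {
    i <- keep[k]
    idx <- which(!is.na(st$cons[i, ]))
    list(id = sprintf("hap%02d", k), idx = idx,
         allele = st$cons[i, idx],
         support = pmax(st$n0[i, idx], st$n1[i, idx]),
         reads = st$members[[i]])
  })
  haplotype_set(haps, fs$n_sites, sites)
}

#' Estimate the fragment error rate against a final haplotype set
#'
#' For every read, the minimum number of mismatches against any haplotype
#' over their shared sites is counted; the rate is total minimum
#' mismatches divided by total compared alleles. Reads overlapping no
#' haplotype are excluded and counted.
#'
#' @param fs the [fragment_set] that was phased.
#' @param hs the resulting [haplotype_set].
#' @return A list with `rate`, `n_mismatch`, `n_compared`, `n_excluded`.
#' @export
estimate_error_rate <- function(fs, hs) {
  if (!length(hs$haplotypes)) stop("haplotype set is empty")
  n <- hs$n_sites
  hv <- lapply(hs$haplotypes, function(h) {
    v <- rep(NA_integer_, n); v[h$idx] <- h$allele; v
  })
  n_mm <- 0L; n_cmp <- 0L; n_exc <- 0L
  for (r in fs$reads) {
    best_mm <- NA_integer_; best_ov <- 0L
    for (v in hv) {
      a <- v[r$idx]
      sh <- !is.na(a)
      ov <- sum(sh)
      if (ov == 0L) next
      mm <- sum(a[sh] != r$allele[sh])
      if (is.na(best_mm) || mm < best_mm ||
          (mm == best_mm && ov > best_ov)) {
        best_mm <- mm; best_ov <- ov
      }
    }
    if (is.na(best_mm)) n_exc <- n_exc + 1L
    else { n_mm <- n_mm + best_mm; n_cmp <- n_cmp + best_ov }
  }
  if (n_exc > 0)
    message("estimate_error_rate: ", n_exc,
            " read(s) overlapped no haplotype")
  list(rate = if (n_cmp > 0) n_mm / n_cmp else NA_real_,
       n_mismatch = n_mm, n_compared = n_cmp, n_excluded = n_exc)
}

#' Haplotype-count profile of a phased set
#'
#' Number of haplotypes keying each site, and the mean over phased sites
#' (sites covered by at least one haplotype).
#'
#' @param hs a [haplotype_set].
#' @return A list with `counts` (integer per site) and `mean` (`NA` for an
#'   empty set).
#' @export
haplotype_count_profile <- function(hs) {
  counts <- integer(hs$n_sites)
  for (h in hs$haplotypes) counts[h$idx] <- counts[h$idx] + 1L
  phased <- counts > 0L
  list(counts = counts,
       mean = if (any(phased)) mean(counts[phased]) else NA_real_)
}

#' Partition cost of a phasing: total irreducible mismatches
#'
#' For the read partition implied by a haplotype set (member reads per
#' haplotype; unplaced reads count as singletons), sums over groups and
#' sites the minority allele count — the same objective the exhaustive
#' small-instance solver [exact_phase_cost()] minimises.
#'
#' @param fs the phased [fragment_set].
#' @param hs the [haplotype_set] produced from it.
#' @return Total mismatch count (non-negative integer).
#' @export
phase_partition_cost <- function(fs, hs) {
  assign_of <- rep(0L, length(fs$reads))
  ids <- vapply(fs$reads, `[[`, character(1), "id")
  for (k in seq_along(hs$haplotypes))
    assign_of[ids %in% hs$haplotypes[[k]]$reads] <- k
  nxt <- length(hs$haplotypes)
  for (i in which(assign_of == 0L)) {        # unplaced reads: singletons
    nxt <- nxt + 1L
    assign_of[i] <- nxt
  }
  total <- 0L
  for (g in unique(assign_of)) {
    rs <- fs$reads[assign_of == g]
    c0 <- integer(fs$n_sites); c1 <- integer(fs$n_sites)
    for (r in rs) {
      c1[r$idx] <- c1[r$idx] + r$allele
      c0[r$idx] <- c0[r$idx] + 1L - r$allele
    }
    total <- total + sum(pmin(c0, c1))
  }
  total
}

#' Exact minimum-mismatch phasing cost for small instances
#'
#' Exhaustively partitions reads into at most `max_groups` haplotype
#' groups (bitmask subset dynamic programming) and returns the minimum
#' total mismatch count, where a group's cost is the minority allele
#' count summed over sites. This is the optimality oracle the greedy
#' phaser is cross-checked against; it is limited to about 20 reads.
#'
#' @param fs a [fragment_set] (or an integer read x site matrix with `NA`
#'   at uncovered sites).
#' @param max_groups maximum number of haplotype groups (default 4).
#' @return Minimum total mismatch count.
#' @export
exact_phase_cost <- function(fs, max_groups = 4) {
  mat <- if (is.matrix(fs)) fs else {
    m <- matrix(NA_integer_, length(fs$reads), fs$n_sites)
    for (i in seq_along(fs$reads))
      m[i, fs$reads[[i]]$idx] <- fs$reads[[i]]$allele
    m
  }
  storage.mode(mat) <- "integer"
  exact_phase_cost_cpp(mat, as.integer(max_groups))
}
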