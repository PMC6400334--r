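#' Population alternate-allele frequencies from genotype calls
#'
#' Frequency is computed from counts of homozygous calls plus half of
#' heterozygous calls: freq = (2 * nHomAlt + nHet) / (2 * nCalled), with
#' missing genotypes excluded from the denominator. Strains with more
#' than `max_admixture` of their genome assigned outside their own
#' population (per the matrix's `admixture` vector) are excluded first.
#'
#' @param gm a [genotype_matrix] with population labels.
#' @param group population label, or a character vector of strain names.
#' @param max_admixture admixture cap for strain inclusion (default 0.01).
#' @return Numeric vector of per-site alt frequencies (`NA` where no
#'   strain is called).
#' @export
population_allele_freq <- function(gm, group, max_admixture = 0.01) {
  strains <- if (all(group %in% gm$strains)) group
  else {
    if (is.null(gm$pop)) stop("genotype matrix has no population labels")
    names(gm$pop)[gm$pop %in% group]
  }
  if (!is.null(gm$admixture)) {
    adm <- gm$admixture[strains]
    adm[is.na(adm)] <- 0
    strains <- strains[adm <= max_admixture]
  }
  if (!length(strains)) stop("no strains left in group after admixture filter")
  calls <- gm$calls[strains, , drop = FALSE]
  called <- colSums(!is.na(calls))
  alt_dose <- colSums(calls, na.rm = TRUE)       # 0/1/2 dosage sums
  out <- alt_dose / (2 * called)
  out[called == 0] <- NA_real_
  out
}

#' Select ancestry-diagnostic sites from two population frequencies
#'
#' A site is diagnostic when one population's alt frequency is at least
#' `hi` while the other's is at most `lo` (nearly fixed difference). The
#' allele typed to each population is recorded.
#'
#' @param freq1,freq2 per-site alt frequencies for the two populations.
#' @param hi,lo frequency thresholds (defaults 0.99 and 0.01).
#' @return A data.frame `site`, `pop1_allele`, `pop2_allele` (0/1 codes;
#'   `pop1_allele` is the allele near-fixed in population 1).
#' @export
select_diagnostic_sites <- function(freq1, freq2, hi = 0.99, lo = 0.01) {
  stopifnot(length(freq1) == length(freq2))
  ok <- !is.na(freq1) & !is.na(freq2)
  sel1 <- ok & freq1 >= hi & freq2 <= lo    # alt typed to pop1
  sel2 <- ok & freq1 <= lo & freq2 >= hi    # alt typed to pop2
  site <- which(sel1 | sel2)
  data.frame(site = site,
             pop1_allele = as.integer(sel1[site]),
             pop2_allele = as.integer(sel2[site]))
}

#' Select group-private alleles
#'
#' An allele is private to a group when its frequency is at least
#' `min_in` there and below `max_out` in every other population. Both
#' alleles of each site are considered; the first qualifying group (in
#' column order) wins a site.
#'
#' @param freq_by_group matrix of per-site alt frequencies, sites in rows,
#'   one column per population (beer groups and all outgroup populations).
#' @param groups column names to scan for private alleles (default: all).
#' @param min_in minimum within-group frequency (default 0.25).
#' @param max_out maximum frequency in any other population (default 0.01).
#' @return A data.frame `site`, `allele` (0/1), `group`.
#' @export
select_group_private_alleles <- function(freq_by_group,
                                         groups = colnames(freq_by_group),
                                         min_in = 0.25, max_out = 0.01) {
  freq_by_group <- as.matrix(freq_by_group)
  if (ncol(freq_by_group) < 2) stop("need at least two populations")
  out <- data.frame(site = integer(0), allele = integer(0),
                    group = character(0))
  taken <- logical(nrow(freq_by_group))
  for (g in groups) {
    others <- setdiff(colnames(freq_by_group), g)
    fg <- freq_by_group[, g]
    fo <- freq_by_group[, others, drop = FALSE]
    complete <- !is.na(fg) & !apply(is.na(fo), 1, any)
    alt_priv <- complete & fg >= min_in & apply(fo < max_out, 1, all)
    ref_priv <- complete & (1 - fg) >= min_in &
      apply((1 - fo) < max_out, 1, all)
    for (allele in c(1L, 0L)) {
      sel <- which(if (allele == 1L) alt_priv else ref_priv)
      sel <- sel[!taken[sel]]
      if (length(sel)) {
        out <- rbind(out, data.frame(site = sel, allele = allele,
                                     group = g))
        taken[sel] <- TRUE
      }
    }
  }
  out[order(out$site), , drop = FALSE]
}

#' Assemble an ancestry panel
#'
#' Combines diagnostic sites and group-private alleles, enforcing that a
#' site appears in at most one of the two maps (diagnostic wins).
#'
#' @param diagnostic result of [select_diagnostic_sites()].
#' @param private result of [select_group_private_alleles()] (optional).
#' @return An object of class `ancestry_panel`.
#' @export
ancestry_panel <- function(diagnostic, private = NULL) {
  if (!is.null(private) && nrow(private)) {
    clash <- private$site %in% diagnostic$site
    private <- private[!clash, , drop = FALSE]
  }
  structure(list(diagnostic = diagnostic, private = private),
            class = "ancestry_panel")
}

#' @export
print.ancestry_panel <- function(x, ...) {
  cat("Ancestry panel:", nrow(x$diagnostic), "diagnostic sites")
  if (!is.null(x$private)) cat(",", nrow(x$private), "group-private alleles")
  cat("\n")
  invisible(x)
}

#' Paint phased haplotypes with ancestry codes
#'
#' Every diagnostic panel site covered by a haplotype is coded "E" (the
#' allele typed to population 1) or "A" (population 2). A haplotype is
#' classified E-pure or A-pure when more than `purity` of its coded sites
#' are one type, mixed otherwise; haplotypes covering no panel site are
#' unclassified.
#'
#' @param hs a [haplotype_set].
#' @param panel an [ancestry_panel] (or a diagnostic-site data.frame).
#' @param purity purity threshold (default 0.95).
#' @return An object of class `painted_haplotypes`: per haplotype the
#'   coded site indices, codes, carried private-allele sites, class and
#'   bp extent.
#' @export
paint <- function(hs, panel, purity = 0.95) {
  diag_tab <- if (inherits(panel, "ancestry_panel")) panel$diagnostic else panel
  priv <- if (inherits(panel, "ancestry_panel")) panel$private else NULL
  pos <- if (!is.null(hs$sites)) hs$sites$pos else seq_len(hs$n_sites)
  chrom <- if (!is.null(hs$sites)) hs$sites$chrom else
    rep("chr", hs$n_sites)
  haps <- lapply(hs$haplotypes, function(h) {
    m <- match(h$idx, diag_tab$site)
    on_panel <- !is.na(m)
    idx <- h$idx[on_panel]
    code <- ifelse(h$allele[on_panel] == diag_tab$pop1_allele[m[on_panel]],
                   "E", "A")
    p_idx <- integer(0)
    if (!is.null(priv) && nrow(priv)) {
      pm <- match(h$idx, priv$site)
      hit <- !is.na(pm) & h$allele == priv$allele[ifelse(is.na(pm), 1L, pm)]
      p_idx <- h$idx[hit]
    }
    cls <- if (!length(code)) "unclassified"
    else {
      fE <- mean(code == "E")
      if (fE > purity) "E-pure"
      else if (1 - fE > purity) "A-pure"
      else "mixed"
    }
    extent_bp <- if (length(h$idx))
      pos[h$idx[length(h$idx)]] - pos[h$idx[1]] else 0
    list(id = h$id, idx = idx, code = code, private_idx = p_idx,
         class = cls, extent_bp = extent_bp,
         chrom = if (length(h$idx)) chrom[h$idx[1]] else NA_character_)
  })
  structure(list(haplotypes = haps, purity = purity, sites = hs$sites,
                 n_sites = hs$n_sites),
            class = "painted_haplotypes")
}

#' @export
print.painted_haplotypes <- function(x, ...) {
  cls <- vapply(x$haplotypes, `[[`, character(1), "class")
  cat("Painted haplotypes:", length(cls), "\n")
  print(table(cls))
  invisible(x)
}

# collapse a code sequence into runs; iteratively drop runs failing the
# filter (shortest first, then smallest span, then leftmost), merging
# flanking same-type runs
.filter_runs <- function(code, pos, min_sites = 1, min_span_bp = 0) {
  if (!length(code)) return(0L)
  runs <- function(cd, po) {
    r <- rle(cd)
    end <- cumsum(r$lengths)
    start <- end - r$lengths + 1L
    data.frame(code = r$values, n = r$lengths,
               span = po[end] - po[start], start = start, end = end)
  }
  cd <- code; po <- pos
  repeat {
    rt <- runs(cd, po)
    fail <- which(rt$n < min_sites | rt$span < min_span_bp)
    if (!length(fail)) return(max(nrow(rt) - 1L, 0L))
    if (length(fail) == nrow(rt)) return(0L)
    k <- fail[order(rt$n[fail], rt$span[fail], fail)][1]
    drop <- rt$start[k]:rt$end[k]
    cd <- cd[-drop]; po <- po[-drop]
  }
}

#' Count ancestry switches under a run filter
#'
#' The haplotype's E/A code sequence is collapsed into runs; runs failing
#' the filter (fewer than `min_sites` sites, or spanning fewer than
#' `min_span_bp` bp) are discarded with their flanking same-type runs
#' merged, and switches are the number of surviving runs minus one.
#'
#' @param painted a [paint()] result.
#' @param min_sites minimum sites per run (default 1).
#' @param min_span_bp minimum bp span per run (default 0).
#' @return Named integer vector of per-haplotype switch counts with a
#'   `total` attribute.
#' @export
count_switches <- function(painted, min_sites = 1, min_span_bp = 0) {
  pos <- if (!is.null(painted$sites)) painted$sites$pos
  else seq_len(painted$n_sites)
  chrom <- if (!is.null(painted$sites)) painted$sites$chrom
  else rep("chr", painted$n_sites)
  out <- vapply(painted$haplotypes, function(h) {
    # switches never span a chromosome boundary
    total <- 0L
    for (ch in unique(chrom[h$idx])) {
      on <- chrom[h$idx] == ch
      total <- total +
        .filter_runs(h$code[on], pos[h$idx][on], min_sites, min_span_bp)
    }
    total
  }, integer(1))
  names(out) <- vapply(painted$haplotypes, `[[`, character(1), "id")
  attr(out, "total") <- sum(out)
  out
}

#' Switch counts under the three standard run filters
#'
#' Counts switches per haplotype with runs of one or more sites, five or
#' more sites, and spanning 4 kb or longer, plus genome-wide totals.
#'
#' @param painted a [paint()] result.
#' @return A data.frame of class `switch_report` with per-haplotype rows
#'   and a `totals` attribute.
#' @export
switch_report <- function(painted) {
  s1 <- count_switches(painted, min_sites = 1)
  s5 <- count_switches(painted, min_sites = 5)
  s4k <- count_switches(painted, min_span_bp = 4000)
  out <- data.frame(haplotype = names(s1), min1site = as.integer(s1),
                    min5sites = as.integer(s5), min4kb = as.integer(s4k))
  attr(out, "totals") <- c(min1site = sum(s1), min5sites = sum(s5),
                           min4kb = sum(s4k))
  class(out) <- c("switch_report", "data.frame")
  out
}

#' @export
print.switch_report <- function(x, ...) {
  NextMethod()
  tot <- attr(x, "totals")
  cat("totals:", paste(names(tot), tot, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Fraction of the genome carried on ancestry-pure haplotypes
#'
#' Base pairs are measured between each haplotype's extent endpoints; the
#' fraction is bp on E-pure or A-pure haplotypes over bp on all
#' classified (non-`unclassified`) haplotypes.
#'
#' @param painted a [paint()] result.
#' @return Fraction in [0, 1], or `NA` when nothing is classified.
#' @export
pure_fraction <- function(painted) {
  cls <- vapply(painted$haplotypes, `[[`, character(1), "class")
  bp <- vapply(painted$haplotypes, `[[`, numeric(1), "extent_bp")
  classified <- cls != "unclassified"
  if (!any(classified) || sum(bp[classified]) == 0) return(NA_real_)
  sum(bp[classified & cls %in% c("E-pure", "A-pure")]) / sum(bp[classified])
}

#' Mean allele copy numbers at fully phased tetraploid sites
#'
#' At heterozygous panel sites covered by exactly four haplotypes, counts
#' the haplotypes carrying the population-2 ("A") typed allele and, at
#' private-allele sites, the private allele; reports the two means.
#'
#' @param hs a [haplotype_set].
#' @param panel an [ancestry_panel].
#' @return A list: `diagnostic_mean`, `diagnostic_n`, `private_mean`,
#'   `private_n`.
#' @export
allele_copy_counts <- function(hs, panel) {
  n <- hs$n_sites
  cnt <- integer(n); alt <- integer(n)
  for (h in hs$haplotypes) {
    cnt[h$idx] <- cnt[h$idx] + 1L
    alt[h$idx] <- alt[h$idx] + h$allele
  }
  four <- cnt == 4L
  het <- alt > 0L & alt < cnt

  dtab <- panel$diagnostic
  dsel <- dtab$site[four[dtab$site] & het[dtab$site]]
  dcop <- if (length(dsel)) {
    a2 <- dtab$pop2_allele[match(dsel, dtab$site)]
    ifelse(a2 == 1L, alt[dsel], 4L - alt[dsel])
  } else integer(0)

  pcop <- integer(0)
  if (!is.null(panel$private) && nrow(panel$private)) {
    ptab <- panel$private
    psel <- ptab$site[four[ptab$site] & het[ptab$site]]
    if (length(psel)) {
      pa <- ptab$allele[match(psel, ptab$site)]
      pcop <- ifelse(pa == 1L, alt[psel], 4L - alt[psel])
    }
  }
  list(diagnostic_mean = if (length(dcop)) mean(dcop) else NA_real_,
       diagnostic_n = length(dcop),
       private_mean = if (length(pcop)) mean(pcop) else NA_real_,
       private_n = length(pcop))
}
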