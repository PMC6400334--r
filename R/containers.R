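#' Site table constructor
#'
#' Builds the ordered table of biallelic SNP sites used throughout the
#' package. Sites must be strictly sorted by (chrom, pos) and carry
#' single-character REF/ALT alleles.
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based coordinates.
#' @param ref,alt single-character reference and alternate alleles.
#' @return A `data.frame` of class `snp_sites` with columns
#'   `chrom`, `pos`, `ref`, `alt`.
#' @export
snp_sites <- function(chrom, pos, ref = "A", alt = "T") {
  n <- length(chrom)
  stopifnot(length(pos) == n)
  pos <- as.integer(pos)
  if (any(pos < 1L)) stop("site positions must be >= 1")
  ref <- rep_len(as.character(ref), n)
  alt <- rep_len(as.character(alt), n)
  if (any(nchar(ref) != 1L) || any(nchar(alt) != 1L))
    stop("only biallelic SNPs with single-character alleles are supported")
  df <- data.frame(chrom = as.character(chrom), pos = pos,
                   ref = ref, alt = alt, stringsAsFactors = FALSE)
  o <- order(df$chrom, df$pos)
  df <- df[o, , drop = FALSE]
  if (anyDuplicated(df[, c("chrom", "pos")]))
    stop("duplicate sites (same chrom and pos)")
  rownames(df) <- NULL
  class(df) <- c("snp_sites", "data.frame")
  df
}

#' Genotype matrix constructor
#'
#' Container for strain-by-site genotype calls with optional population
#' labels. Genotypes are coded 0 = homozygous reference, 1 = heterozygous,
#' 2 = homozygous alternate, `NA` = missing.
#'
#' @param calls integer matrix, strains in rows, sites in columns.
#' @param sites a [snp_sites] table with one row per column of `calls`.
#' @param pop optional named character vector: strain -> population label.
#' @param admixture optional named numeric vector: strain -> fraction of the
#'   genome assigned to populations other than `pop` (used to exclude
#'   admixed strains from allele-frequency panels).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, sites, pop = NULL, admixture = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (ncol(calls) != nrow(sites))
    stop("ncol(calls) must equal nrow(sites)")
  if (is.null(rownames(calls)))
    rownames(calls) <- paste0("strain", seq_len(nrow(calls)))
  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype codes must be 0, 1, 2 or NA")
  if (!is.null(pop)) {
    if (is.null(names(pop))) stop("pop must be named by strain")
    pop <- pop[intersect(names(pop), rownames(calls))]
  }
  if (!is.null(admixture)) {
    admixture <- admixture[intersect(names(admixture), rownames(calls))]
  }
  structure(list(calls = calls, sites = sites,
                 strains = rownames(calls),
                 pop = pop, admixture = admixture),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix:", nrow(x$calls), "strains x", ncol(x$calls),
      "biallelic SNPs\n")
  cat("  chromosomes:", length(unique(x$sites$chrom)),
      " missing calls:", sum(is.na(x$calls)), "\n")
  if (!is.null(x$pop)) {
    tb <- table(x$pop)
    cat("  populations:",
        paste(names(tb), tb, sep = ":", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-site read counts
#'
#' Reference and alternate read-depth matrices aligned with a
#' [genotype_matrix] (strains in rows, sites in columns).
#'
#' @param ref,alt non-negative integer matrices of identical dimension.
#' @return An object of class `site_read_counts`.
#' @export
site_read_counts <- function(ref, alt) {
  ref <- as.matrix(ref); alt <- as.matrix(alt)
  storage.mode(ref) <- "integer"; storage.mode(alt) <- "integer"
  if (!identical(dim(ref), dim(alt)))
    stop("ref and alt count matrices must have identical dimensions")
  if (any(ref < 0L, na.rm = TRUE) || any(alt < 0L, na.rm = TRUE))
    stop("read counts must be non-negative")
  structure(list(ref = ref, alt = alt), class = "site_read_counts")
}

#' Fragment set constructor
#'
#' Sparse long-read allele observations: for each read, the (1-based) site
#' indices it covers and the allele (0 = REF, 1 = ALT) observed at each.
#'
#' @param reads list; each element a list with components `id` (character),
#'   `idx` (strictly increasing integer site indices) and `allele`
#'   (0/1 integers, same length as `idx`).
#' @param n_sites number of sites in the site list the indices refer into.
#' @return An object of class `fragment_set`.
#' @export
fragment_set <- function(reads, n_sites) {
  for (r in reads) {
    stopifnot(length(r$idx) == length(r$allele))
    if (length(r$idx) && (is.unsorted(r$idx, strictly = TRUE)))
      stop("site indices within a read must be strictly increasing")
    if (length(r$idx) && max(r$idx) > n_sites)
      stop("fragment site index beyond site list")
    if (length(r$allele) && !all(r$allele %in% c(0L, 1L)))
      stop("fragment alleles must be 0 or 1")
  }
  structure(list(reads = reads, n_sites = as.integer(n_sites)),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  nv <- vapply(x$reads, function(r) length(r$idx), integer(1))
  cat("Fragment set:", length(x$reads), "reads over", x$n_sites, "sites\n")
  if (length(nv))
    cat("  sites per read: median", stats::median(nv),
        " range", min(nv), "-", max(nv), "\n")
  invisible(x)
}

#' Haplotype set constructor
#'
#' A variable number of phased haplotypes, each a sparse 0/1 allele vector
#' with per-site read support.
#'
#' @param haplotypes list; each element a list with `id`, `idx` (increasing
#'   integer site indices), `allele` (0/1), `support` (reads backing the
#'   consensus allele at each site), and `reads` (ids of member reads).
#' @param n_sites length of the underlying site list.
#' @param sites optional [snp_sites] table for genomic coordinates.
#' @return An object of class `haplotype_set`.
#' @export
haplotype_set <- function(haplotypes, n_sites, sites = NULL) {
  for (h in haplotypes) {
    stopifnot(length(h$idx) == length(h$allele))
    if (length(h$idx) && is.unsorted(h$idx, strictly = TRUE))
      stop("haplotype site indices must be strictly increasing")
  }
  structure(list(haplotypes = haplotypes, n_sites = as.integer(n_sites),
                 sites = sites),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("Haplotype set:", length(x$haplotypes), "haplotypes over",
      x$n_sites, "sites\n")
  prof <- haplotype_count_profile(x)
  if (!is.na(prof$mean))
    cat("  mean haplotypes per phased site:", round(prof$mean, 2), "\n")
  invisible(x)
}

#' @export
summary.haplotype_set <- function(object, ...) {
  nh <- length(object$haplotypes)
  len <- vapply(object$haplotypes, function(h) length(h$idx), integer(1))
  prof <- haplotype_count_profile(object)
  out <- list(n_haplotypes = nh, sites_per_haplotype = summary(len),
              mean_haplotypes_per_site = prof$mean)
  class(out) <- "summary.haplotype_set"
  out
}

#' @export
print.summary.haplotype_set <- function(x, ...) {
  cat("Haplotypes:", x$n_haplotypes, "\n")
  cat("Sites per haplotype:\n"); print(x$sites_per_haplotype)
  cat("Mean haplotypes at phased sites:", round(x$mean_haplotypes_per_site, 3), "\n")
  invisible(x)
}
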