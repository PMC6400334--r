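#' Read genotypes and read counts from a VCF file
#'
#' Parses a VCF 4.x file (via vcfR), keeping biallelic SNP records only.
#' Multiallelic or indel records are skipped and counted in a message.
#' Genotypes are taken from the GT field (phased separators accepted,
#' phase ignored; half calls treated as missing); per-site read counts are
#' taken from the AD field where present.
#'
#' @param path path to a VCF (optionally gzipped) file.
#' @return A list with components `genotypes` (a [genotype_matrix]) and
#'   `counts` (a [site_read_counts], or `NULL` when no AD field exists).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  fmt <- colnames(v@gt)
  if (is.null(v@gt) || !"FORMAT" %in% fmt)
    stop("VCF has no genotype (FORMAT/GT) data")
  has_gt <- grepl("(^|:)GT(:|$)", v@gt[, "FORMAT"])
  if (!all(has_gt)) stop("GT field absent from FORMAT")

  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  keep <- nchar(ref) == 1L & !is.na(alt) & nchar(alt) == 1L & !grepl(",", alt)
  n_skip <- sum(!keep)
  if (n_skip > 0)
    message("read_vcf: skipped ", n_skip,
            " non-biallelic-SNP record(s)")
  if (!any(keep)) stop("no biallelic SNP records in ", path)

  sites <- snp_sites(fix[keep, "CHROM"], as.integer(fix[keep, "POS"]),
                     ref[keep], alt[keep])
  # recover permutation applied by snp_sites' (chrom,pos) sort
  kept <- data.frame(chrom = fix[keep, "CHROM"],
                     pos = as.integer(fix[keep, "POS"]))
  o <- order(kept$chrom, kept$pos)

  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE][o, , drop = FALSE]
  code <- .gt_to_code(gt)
  calls <- t(code)

  counts <- NULL
  if (any(grepl("(^|:)AD(:|$)", v@gt[, "FORMAT"]))) {
    ad <- vcfR::extract.gt(v, element = "AD")[keep, , drop = FALSE][o, , drop = FALSE]
    refc <- t(.ad_field(ad, 1L))
    altc <- t(.ad_field(ad, 2L))
    counts <- site_read_counts(refc, altc)
  }
  list(genotypes = genotype_matrix(calls, sites), counts = counts)
}

.gt_to_code <- function(gt) {
  g <- gsub("\\|", "/", gt)
  code <- matrix(NA_integer_, nrow(g), ncol(g), dimnames = dimnames(g))
  code[g %in% c("0/0", "0")] <- 0L
  code[g %in% c("0/1", "1/0")] <- 1L
  code[g %in% c("1/1", "1")] <- 2L
  code
}

.ad_field <- function(ad, k) {
  out <- matrix(NA_integer_, nrow(ad), ncol(ad), dimnames = dimnames(ad))
  ok <- !is.na(ad) & ad != "."
  if (any(ok)) {
    parts <- strsplit(ad[ok], ",", fixed = TRUE)
    out[ok] <- suppressWarnings(
      vapply(parts, function(p) as.integer(p[k]), integer(1)))
  }
  out[is.na(out)] <- 0L
  out
}

#' Write a genotype matrix (and optional AD counts) as VCF
#'
#' @param gm a [genotype_matrix].
#' @param path output path.
#' @param counts optional [site_read_counts] written as the AD subfield.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, counts = NULL) {
  s <- gm$sites
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  fmt <- "GT"
  if (!is.null(counts)) {
    hdr <- c(hdr,
      '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">')
    fmt <- "GT:AD"
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", gm$strains),
                      collapse = "\t"))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[gm$calls + 1L],
                   nrow = nrow(gm$calls))
  gt_str[is.na(gm$calls)] <- "./."
  if (!is.null(counts)) {
    gt_str <- matrix(paste0(gt_str, ":", counts$ref, ",", counts$alt),
                     nrow = nrow(gm$calls))
  }
  body <- vapply(seq_len(nrow(s)), function(j) {
    paste(c(s$chrom[j], s$pos[j], ".", s$ref[j], s$alt[j], ".", "PASS", ".",
            fmt, gt_str[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read long-read allele observations from a HapCUT2 fragment file
#'
#' Each line holds one read: a block count, the read id, then for each
#' block a 1-based start SNP index and a 0/1 allele string, and finally a
#' Phred+33 quality string with one character per observed allele.
#' Alleles with base quality below `min_base_quality` are dropped, and
#' reads left covering fewer than two SNPs are discarded.
#'
#' @param path fragment file path.
#' @param n_sites number of sites in the VCF the indices refer into.
#' @param min_base_quality minimum base quality (default 10).
#' @return A [fragment_set].
#' @export
read_fragments <- function(path, n_sites, min_base_quality = 10) {
  if (!file.exists(path)) stop("fragment file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("[ \t\r]+$", "", lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty fragment file: ", path)
    return(fragment_set(list(), n_sites))
  }
  reads <- vector("list", length(lines))
  n_drop <- 0L
  for (i in seq_along(lines)) {
    tok <- strsplit(lines[i], "[ \t]+")[[1]]
    nb <- suppressWarnings(as.integer(tok[1]))
    if (is.na(nb) || length(tok) != 2L + 2L * nb + 1L)
      stop("malformed fragment line ", i)
    id <- tok[2]
    idx <- integer(0); allele <- integer(0)
    for (b in seq_len(nb)) {
      start <- as.integer(tok[1L + 2L * b])
      astr <- tok[2L + 2L * b]
      if (grepl("[^01]", astr))
        stop("fragment allele characters must be 0/1 (line ", i, ")")
      a <- as.integer(strsplit(astr, "")[[1]])
      idx <- c(idx, seq.int(start, length.out = length(a)))
      allele <- c(allele, a)
    }
    if (max(idx) > n_sites)
      stop("fragment SNP index ", max(idx), " beyond site list (line ", i, ")")
    qual <- utf8ToInt(tok[length(tok)]) - 33L
    if (length(qual) != length(allele))
      stop("quality string length mismatch (line ", i, ")")
    keep <- qual >= min_base_quality
    idx <- idx[keep]; allele <- allele[keep]
    if (length(idx) < 2L) { n_drop <- n_drop + 1L; next }
    reads[[i]] <- list(id = id, idx = idx, allele = allele)
  }
  reads <- reads[!vapply(reads, is.null, logical(1))]
  if (n_drop > 0)
    message("read_fragments: dropped ", n_drop,
            " read(s) covering <2 SNPs after quality filtering")
  fragment_set(reads, n_sites)
}

#' Write a fragment set in HapCUT2 fragment format
#'
#' @param fs a [fragment_set].
#' @param path output path.
#' @param base_quality Phred quality written for every allele (default 30).
#' @return `path`, invisibly.
#' @export
write_fragments <- function(fs, path, base_quality = 30) {
  qc <- intToUtf8(base_quality + 33L)
  lines <- vapply(fs$reads, function(r) {
    # split into maximal runs of consecutive indices (blocks)
    brk <- c(0L, which(diff(r$idx) != 1L), length(r$idx))
    blocks <- character(0)
    for (b in seq_len(length(brk) - 1L)) {
      sel <- (brk[b] + 1L):brk[b + 1L]
      blocks <- c(blocks, as.character(r$idx[sel[1]]),
                  paste(r$allele[sel], collapse = ""))
    }
    paste(c((length(brk) - 1L), r$id, blocks,
            strrep(qc, length(r$idx))), collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write phased (optionally painted) haplotypes as a TSV table
#'
#' One row per site covered by at least one haplotype, columns `chrom`,
#' `pos`, one 0/1/"." allele column per haplotype and, when `painted` is
#' supplied, one E/A/"." ancestry-code column per haplotype.
#'
#' @param hs a [haplotype_set] with a `sites` table.
#' @param path output path.
#' @param painted optional result of [paint()] for the same set.
#' @return `path`, invisibly.
#' @export
write_haplotypes <- function(hs, path, painted = NULL) {
  ids <- vapply(hs$haplotypes, `[[`, character(1), "id")
  cov <- sort(unique(unlist(lapply(hs$haplotypes, `[[`, "idx"))))
  hdr <- c("chrom", "pos", ids)
  if (!is.null(painted)) hdr <- c(hdr, paste0(ids, "_anc"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(hdr, collapse = "\t"), con)
  if (length(cov)) {
    amat <- matrix(".", length(cov), length(ids))
    for (k in seq_along(hs$haplotypes)) {
      h <- hs$haplotypes[[k]]
      amat[match(h$idx, cov), k] <- as.character(h$allele)
    }
    rows <- cbind(hs$sites$chrom[cov], hs$sites$pos[cov], amat)
    if (!is.null(painted)) {
      cmat <- matrix(".", length(cov), length(ids))
      for (k in seq_along(painted$haplotypes)) {
        p <- painted$haplotypes[[k]]
        if (length(p$idx)) cmat[match(p$idx, cov), k] <- p$code
      }
      rows <- cbind(rows, cmat)
    }
    writeLines(apply(rows, 1, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a haplotype TSV written by [write_haplotypes()]
#'
#' @param path TSV path.
#' @return A [haplotype_set]; site indices refer into the site table
#'   reconstructed from the file's own rows.
#' @export
read_haplotypes <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE)
  anc <- grepl("_anc$", names(tab))
  hap_cols <- setdiff(names(tab)[!anc], c("chrom", "pos"))
  sites <- snp_sites(tab$chrom, as.integer(tab$pos))
  haps <- lapply(hap_cols, function(id) {
    v <- tab[[id]]
    j <- which(v != ".")
    list(id = id, idx = j, allele = as.integer(v[j]),
         support = rep(1L, length(j)), reads = character(0))
  })
  haplotype_set(haps, nrow(sites), sites)
}

#' Read a strain-to-population assignment table
#'
#' Expects TSV columns `strain`, `population` and optionally
#' `ancestry_fraction` (fraction of the genome assigned to the named
#' population; strains below 0.99 are treated as admixed by panel
#' builders with their default 1% admixture cap).
#'
#' @param path TSV path.
#' @return A data.frame with those columns.
#' @export
read_pop_assignments <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("strain", "population")
  if (!all(need %in% names(tab)))
    stop("assignment table must have columns: ", paste(need, collapse = ", "))
  if (!"ancestry_fraction" %in% names(tab)) tab$ancestry_fraction <- 1
  tab
}
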