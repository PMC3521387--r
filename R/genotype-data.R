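#' Construct a genotype matrix
#'
#' Container for biallelic SNP genotypes coded as counts of the variant allele:
#' `0` = homozygous wild (w), `1` = heterozygous (h), `2` = homozygous variant
#' (v), `-9` = missing. Rows are SNPs, columns are individuals.
#'
#' @param genotypes Integer matrix (SNPs x individuals) with codes in
#'   `{0, 1, 2, -9}`.
#' @param snp_info Data frame with one row per SNP: columns `snp_id`, `chrom`,
#'   `pos` (0-based base-pair position), `allele_wild`, `allele_variant`, and
#'   optionally `monomorphic` (logical).
#' @param sample_ids Character vector of unique individual identifiers, one per
#'   column of `genotypes`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `genotypes`, `snp_info` (tibble), and `sample_ids`.
#' @export
#' @examples
#' gm <- genotype_matrix(
#'   matrix(c(0L, 1L, 2L, 0L, 0L, 1L), nrow = 2, byrow = TRUE),
#'   tibble::tibble(
#'     snp_id = c("rs1", "rs2"), chrom = "1", pos = c(100L, 200L),
#'     allele_wild = c("A", "C"), allele_variant = c("G", "T")
#'   ),
#'   c("s1", "s2", "s3")
#' )
#' gm
genotype_matrix <- function(genotypes, snp_info, sample_ids) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  snp_info <- tibble::as_tibble(snp_info)
  needed <- c("snp_id", "chrom", "pos", "allele_wild", "allele_variant")
  missing_cols <- setdiff(needed, names(snp_info))
  if (length(missing_cols) > 0) {
    stop("snp_info lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"monomorphic" %in% names(snp_info)) {
    snp_info$monomorphic <- is.na(snp_info$allele_variant)
  }
  if (nrow(snp_info) != nrow(genotypes)) {
    stop("snp_info rows must match genotype rows", call. = FALSE)
  }
  if (length(sample_ids) != ncol(genotypes)) {
    stop("sample_ids must match genotype columns", call. = FALSE)
  }
  if (anyDuplicated(snp_info$snp_id)) stop("snp_ids must be unique", call. = FALSE)
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique", call. = FALSE)
  bad <- !(genotypes %in% c(0L, 1L, 2L, -9L))
  if (any(bad)) {
    idx <- which(bad)[1]
    stop("invalid genotype code ", genotypes[idx], " at SNP ",
         snp_info$snp_id[(idx - 1) %% nrow(genotypes) + 1], call. = FALSE)
  }
  if (any(snp_info$pos < 0)) stop("positions must be non-negative", call. = FALSE)
  dimnames(genotypes) <- list(snp_info$snp_id, sample_ids)
  structure(
    list(genotypes = genotypes, snp_info = snp_info,
         sample_ids = as.character(sample_ids)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$genotypes), " SNPs x ",
      ncol(x$genotypes), " individuals\n", sep = "")
  n_miss <- sum(x$genotypes == -9L)
  if (n_miss > 0) cat("  missing genotypes: ", n_miss, "\n", sep = "")
  print(utils::head(x$snp_info, 5))
  invisible(x)
}

#' Number of SNPs / samples in a genotype matrix
#' @param gm A [genotype_matrix()].
#' @return Integer count.
#' @export
n_snps <- function(gm) nrow(gm$genotypes)

#' @rdname n_snps
#' @export
n_samples <- function(gm) ncol(gm$genotypes)

#' Construct case/control phenotype labels
#'
#' @param sample_ids Character vector of individual identifiers.
#' @param status Character or factor vector with values `"case"` or
#'   `"control"`, aligned with `sample_ids`.
#'
#' @return A tibble with columns `sample_id` and `status` (factor with levels
#'   control, case).
#' @export
phenotype_labels <- function(sample_ids, status) {
  status <- as.character(status)
  bad <- !status %in% c("case", "control")
  if (any(bad)) {
    stop("phenotype status must be 'case' or 'control'; got '",
         status[which(bad)[1]], "'", call. = FALSE)
  }
  if (length(sample_ids) != length(status)) {
    stop("sample_ids and status lengths differ", call. = FALSE)
  }
  ph <- tibble::tibble(
    sample_id = as.character(sample_ids),
    status = factor(status, levels = c("control", "case"))
  )
  if (sum(ph$status == "case") < 1 || sum(ph$status == "control") < 1) {
    stop("need at least one case and one control", call. = FALSE)
  }
  ph
}

check_phenotypes <- function(gm, phenotypes) {
  if (!setequal(phenotypes$sample_id, gm$sample_ids)) {
    stop("phenotype sample ids do not match the genotype matrix", call. = FALSE)
  }
  # align to genotype column order
  phenotypes[match(gm$sample_ids, phenotypes$sample_id), , drop = FALSE]
}

#' Assign wild/variant allele labels from allele tallies
#'
#' The wild allele at each SNP is the major allele in the pooled case+control
#' sample; ties are broken lexicographically (the alphabetically first allele is
#' wild). SNPs with a single observed allele are flagged monomorphic. More than
#' two observed alleles is an error: the pairwise statistic is defined on
#' biallelic markers only.
#'
#' @param allele_counts A list with one element per SNP, each a named integer
#'   vector of allele counts (missing alleles excluded).
#'
#' @return A tibble with columns `allele_wild`, `allele_variant` (NA when
#'   monomorphic), and `monomorphic`.
#' @export
#' @examples
#' assign_alleles(list(c(A = 120, G = 80), c(C = 50, T = 50), c(A = 10)))
assign_alleles <- function(allele_counts) {
  rows <- purrr::map(allele_counts, function(cnt) {
    cnt <- cnt[cnt > 0]
    if (length(cnt) > 2) {
      stop("more than two alleles observed (",
           paste(names(cnt), collapse = ","), "); biallelic markers only",
           call. = FALSE)
    }
    if (length(cnt) == 0) {
      return(tibble::tibble(allele_wild = NA_character_,
                            allele_variant = NA_character_, monomorphic = TRUE))
    }
    if (length(cnt) == 1) {
      return(tibble::tibble(allele_wild = names(cnt),
                            allele_variant = NA_character_, monomorphic = TRUE))
    }
    # major allele is wild; lexicographic tie-break
    ord <- order(-cnt, names(cnt))
    tibble::tibble(allele_wild = names(cnt)[ord[1]],
                   allele_variant = names(cnt)[ord[2]], monomorphic = FALSE)
  })
  dplyr::bind_rows(rows)
}

#' Read genotypes from PLINK text files (.ped/.map)
#'
#' The six leading .ped columns are FID, IID, PAT, MAT, SEX, PHENO; genotypes
#' follow as allele pairs, one pair per .map row. Phenotype must be 1 (control)
#' or 2 (case). The missing-allele symbol is `"0"`; a pair containing it is
#' coded `-9`. Map positions (1-based) are converted to 0-based on read.
#' Allele coding follows [assign_alleles()].
#'
#' @param ped_path Path to the .ped file.
#' @param map_path Path to the .map file.
#'
#' @return A list with elements `genotypes` (a [genotype_matrix()]) and
#'   `phenotypes` (a tibble as from [phenotype_labels()]).
#' @export
read_plink_text <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("ped file not found: ", ped_path, call. = FALSE)
  if (!file.exists(map_path)) stop("map file not found: ", map_path, call. = FALSE)
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "pos"))
  n_snp <- nrow(map)
  if (n_snp == 0) stop("no SNPs in map file", call. = FALSE)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("no individuals in ped file", call. = FALSE)
  fields <- strsplit(trimws(lines), "[ \t]+")
  expected <- 6 + 2 * n_snp
  lens <- lengths(fields)
  if (any(lens != expected)) {
    bad <- which(lens != expected)[1]
    stop("malformed .ped line ", bad, ": expected ", expected,
         " fields, found ", lens[bad], call. = FALSE)
  }
  ped <- do.call(rbind, fields)
  pheno <- ped[, 6]
  if (!all(pheno %in% c("1", "2"))) {
    bad <- which(!pheno %in% c("1", "2"))[1]
    stop("phenotype must be 1 (control) or 2 (case); line ", bad,
         " has '", pheno[bad], "'", call. = FALSE)
  }
  sample_ids <- ped[, 2]
  a1 <- t(ped[, 6 + 2 * seq_len(n_snp) - 1, drop = FALSE])  # n_snp x n_ind
  a2 <- t(ped[, 6 + 2 * seq_len(n_snp), drop = FALSE])

  counts <- lapply(seq_len(n_snp), function(i) {
    al <- c(a1[i, ], a2[i, ])
    al <- al[al != "0"]
    table_to_named(al)
  })
  alleles <- assign_alleles(counts)

  miss <- a1 == "0" | a2 == "0"
  codes <- (a1 == rep(alleles$allele_variant, ncol(a1))) +
    (a2 == rep(alleles$allele_variant, ncol(a2)))
  codes[is.na(codes)] <- 0          # monomorphic: variant NA -> all wild
  codes[miss] <- -9L
  storage.mode(codes) <- "integer"

  snp_info <- tibble::tibble(
    snp_id = map$snp_id, chrom = as.character(map$chrom),
    pos = as.integer(map$pos) - 1L,
    allele_wild = alleles$allele_wild, allele_variant = alleles$allele_variant,
    monomorphic = alleles$monomorphic
  )
  list(
    genotypes = genotype_matrix(codes, snp_info, sample_ids),
    phenotypes = phenotype_labels(sample_ids,
                                  ifelse(pheno == "2", "case", "control"))
  )
}

table_to_named <- function(x) {
  tb <- table(x)
  stats::setNames(as.integer(tb), names(tb))
}

#' Read genotypes from the package's TSV dialect
#'
#' Tab-separated, `#`-comment lines ignored. Header: `snp_id`, `chrom`, `pos`,
#' `allele_wild`, `allele_variant`, then one column per sample id. Body rows
#' hold integer codes in `{0, 1, 2, -9}`. The labels file is tab-separated with
#' columns `sample_id` and `status` (`case`/`control`).
#'
#' @param path Path to the genotype TSV.
#' @param labels_path Path to the phenotype labels TSV.
#'
#' @return A list with elements `genotypes` and `phenotypes`, as for
#'   [read_plink_text()].
#' @export
read_genotype_tsv <- function(path, labels_path) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if (nrow(tab) == 0) stop("no SNPs in genotype file", call. = FALSE)
  meta_cols <- c("snp_id", "chrom", "pos", "allele_wild", "allele_variant")
  if (!all(meta_cols %in% names(tab))) {
    stop("genotype TSV must begin with columns ",
         paste(meta_cols, collapse = ", "), call. = FALSE)
  }
  sample_ids <- setdiff(names(tab), meta_cols)
  if (length(sample_ids) == 0) stop("no sample columns in genotype file", call. = FALSE)
  codes <- as.matrix(tab[, sample_ids])
  bad <- !(codes %in% c(0, 1, 2, -9))
  dim(bad) <- dim(codes)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop("invalid genotype code '", codes[idx[1], idx[2]], "' at SNP ",
         tab$snp_id[idx[1]], ", sample ", sample_ids[idx[2]], call. = FALSE)
  }
  snp_info <- tab[, meta_cols]
  snp_info$chrom <- as.character(snp_info$chrom)
  snp_info$pos <- as.integer(snp_info$pos)
  snp_info$monomorphic <- is.na(snp_info$allele_variant)
  gm <- genotype_matrix(codes, snp_info, sample_ids)

  lab <- readr::read_tsv(labels_path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if (!all(c("sample_id", "status") %in% names(lab))) {
    stop("labels file must have columns sample_id and status", call. = FALSE)
  }
  ph <- phenotype_labels(lab$sample_id, lab$status)
  ph <- check_phenotypes(gm, ph)
  list(genotypes = gm, phenotypes = ph)
}

#' Write genotypes / phenotype labels in the TSV dialect
#'
#' @param gm A [genotype_matrix()].
#' @param phenotypes A tibble as from [phenotype_labels()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_genotype_tsv <- function(gm, path) {
  tab <- dplyr::bind_cols(
    gm$snp_info[, c("snp_id", "chrom", "pos", "allele_wild", "allele_variant")],
    tibble::as_tibble(gm$genotypes, .name_repair = "minimal")
  )
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @export
write_phenotype_tsv <- function(phenotypes, path) {
  readr::write_tsv(
    dplyr::mutate(phenotypes, status = as.character(.data$status)),
    path, progress = FALSE
  )
  invisible(path)
}

#' Per-SNP minor allele frequency
#'
#' Variant-allele frequency is computed over all non-missing genotypes in the
#' pooled case+control sample; the MAF is the smaller of that frequency and its
#' complement.
#'
#' @param gm A [genotype_matrix()].
#' @return A tibble with columns `snp_id`, `maf`, `n_obs`.
#' @export
snp_maf <- function(gm) {
  g <- gm$genotypes
  obs <- g != -9L
  n_obs <- rowSums(obs)
  var_count <- rowSums(g * obs * (g != -9L))   # sum of codes over observed
  q <- ifelse(n_obs > 0, var_count / (2 * n_obs), NA_real_)
  tibble::tibble(
    snp_id = gm$snp_info$snp_id,
    maf = unname(pmin(q, 1 - q)),
    n_obs = unname(as.integer(n_obs))
  )
}

#' Filter SNPs by minor allele frequency
#'
#' Retains SNPs with MAF strictly greater than `threshold` (the common
#' `MAF > 0.05` marker-quality filter), computed over the pooled sample.
#'
#' @param gm A [genotype_matrix()].
#' @param threshold MAF threshold in `[0, 0.5)`. Default 0.05.
#' @return A filtered [genotype_matrix()]; may have zero SNPs.
#' @export
filter_maf <- function(gm, threshold = 0.05) {
  stopifnot(threshold >= 0, threshold < 0.5)
  keep <- !is.na(snp_maf(gm)$maf) & snp_maf(gm)$maf > threshold
  subset_snps(gm, which(keep))
}

subset_snps <- function(gm, idx) {
  structure(
    list(genotypes = gm$genotypes[idx, , drop = FALSE],
         snp_info = gm$snp_info[idx, , drop = FALSE],
         sample_ids = gm$sample_ids),
    class = "genotype_matrix"
  )
}

#' Construct a region set for gene-only filtering
#'
#' Intervals are 0-based, half-open `[start, end)`. The flank (default 10 kb)
#' is applied on both sides when filtering, clipped at zero.
#'
#' @param chrom,start,end Parallel vectors defining the intervals.
#' @param flank Non-negative flank in base pairs added to each side.
#' @return A tibble of class `region_set` with columns `chrom`, `start`, `end`
#'   and a `flank` attribute.
#' @export
region_set <- function(chrom, start, end, flank = 10000) {
  stopifnot(flank >= 0)
  rs <- tibble::tibble(chrom = as.character(chrom),
                       start = as.numeric(start), end = as.numeric(end))
  exp_start <- pmax(rs$start - flank, 0)
  exp_end <- rs$end + flank
  if (any(exp_start >= exp_end)) stop("empty interval after flank expansion", call. = FALSE)
  attr(rs, "flank") <- flank
  class(rs) <- c("region_set", class(rs))
  rs
}

#' Read a BED3 file as a region set
#'
#' @param path Path to a BED3 file (chrom, start, end; 0-based half-open).
#' @param flank Flank in bp applied at filtering time (default 10000).
#' @return A [region_set()].
#' @export
read_bed_regions <- function(path, flank = 10000) {
  bed <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end"))
  region_set(bed$chrom, bed$start, bed$end, flank = flank)
}

#' Restrict a genotype matrix to SNPs near annotated regions
#'
#' A SNP is retained when its position falls within any interval after
#' expanding each interval by the region set's flank on both sides (clipped at
#' zero). Coordinates of both inputs must share one genome build; this is the
#' caller's responsibility. SNP order is preserved.
#'
#' @param gm A [genotype_matrix()].
#' @param regions A [region_set()].
#' @return A filtered [genotype_matrix()].
#' @export
filter_regions <- function(gm, regions) {
  flank <- attr(regions, "flank") %||% 0
  start <- pmax(regions$start - flank, 0)
  end <- regions$end + flank
  gchrom <- gm$snp_info$chrom
  unmatched <- setdiff(unique(gchrom), unique(regions$chrom))
  if (length(unmatched) > 0) {
    warning("chromosome label(s) absent from region set: ",
            paste(unmatched, collapse = ", "), call. = FALSE)
  }
  keep <- logical(n_snps(gm))
  for (ch in intersect(unique(gchrom), unique(regions$chrom))) {
    ri <- regions$chrom == ch
    gi <- which(gchrom == ch)
    pos <- gm$snp_info$pos[gi]
    s <- start[ri]; e <- end[ri]
    inside <- vapply(pos, function(p) any(p >= s & p < e), logical(1))
    keep[gi] <- inside
  }
  subset_snps(gm, which(keep))
}
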