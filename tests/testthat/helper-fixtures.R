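# Fixture builders and independent oracles shared by the test files.

# Random genotype matrix with optional missingness.
random_genotype_matrix <- function(n_snp, n_ind, miss_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- matrix(sample(0:2, n_snp * n_ind, replace = TRUE), n_snp, n_ind)
  if (miss_rate > 0) {
    g[stats::runif(length(g)) < miss_rate] <- -9L
  }
  storage.mode(g) <- "integer"
  genotype_matrix(
    g,
    tibble::tibble(
      snp_id = sprintf("rs%03d", seq_len(n_snp)), chrom = "1",
      pos = as.integer(seq_len(n_snp) * 100L),
      allele_wild = "A", allele_variant = "G", monomorphic = FALSE
    ),
    sprintf("s%03d", seq_len(n_ind))
  )
}

random_phenotypes <- function(gm, n_case = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_samples(gm)
  if (is.null(n_case)) n_case <- floor(n / 2)
  status <- sample(c(rep("case", n_case), rep("control", n - n_case)))
  phenotype_labels(gm$sample_ids, status)
}

# Independent individual-level oracle for rho: the second-moment ratio of the
# -1/0/+1 encoded genotypes over the group's pairwise-complete individuals.
rho_oracle <- function(gx, gy, mask) {
  x <- encode_genotypes(gx)[mask]
  y <- encode_genotypes(gy)[mask]
  use <- !is.na(x) & !is.na(y)
  x <- x[use]; y <- y[use]
  if (length(x) == 0) return(NA_real_)
  den <- sqrt(mean(x^2) * mean(y^2))
  if (den == 0) return(NA_real_)
  mean(x * y) / den
}

# Nested-loop joint-table counting oracle.
joint_table_oracle <- function(gx, gy, mask) {
  counts <- matrix(0, 3, 3)
  n_used <- 0
  for (k in seq_along(gx)) {
    if (!mask[k] || gx[k] == -9L || gy[k] == -9L) next
    counts[gx[k] + 1, gy[k] + 1] <- counts[gx[k] + 1, gy[k] + 1] + 1
    n_used <- n_used + 1
  }
  list(p = counts / n_used, n_used = n_used)
}

# Write a small .ped/.map pair from allele-pair character matrices.
write_ped_map <- function(dir, alleles1, alleles2, pheno, snp_ids = NULL,
                          pos = NULL) {
  n_snp <- nrow(alleles1); n_ind <- ncol(alleles1)
  if (is.null(snp_ids)) snp_ids <- sprintf("rs%d", seq_len(n_snp))
  if (is.null(pos)) pos <- seq_len(n_snp) * 1000
  ped <- file.path(dir, "fix.ped"); map <- file.path(dir, "fix.map")
  writeLines(sprintf("1 %s 0 %d", snp_ids, pos), map)
  lines <- vapply(seq_len(n_ind), function(s) {
    gt <- paste(rbind(alleles1[, s], alleles2[, s]), collapse = " ")
    paste("F", sprintf("ind%02d", s), "0", "0", "1", pheno[s], gt)
  }, character(1))
  writeLines(lines, ped)
  list(ped = ped, map = map)
}

# Genotypes for a SNP pair with known haplotype-level LD under HWE:
# haplotype frequencies from allele frequencies p1, p2 and correlation r,
# genotype = sum of two independent haplotypes.
simulate_ld_pair <- function(n, p1, p2, r) {
  d <- r * sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  h <- c(`11` = p1 * p2 + d, `10` = p1 * (1 - p2) - d,
         `01` = (1 - p1) * p2 - d, `00` = (1 - p1) * (1 - p2) + d)
  stopifnot(all(h > -1e-12))
  h <- pmax(h, 0); h <- h / sum(h)
  hap <- matrix(sample(4, 2 * n, replace = TRUE, prob = h), ncol = 2)
  a1 <- c(1, 1, 0, 0)[hap]; dim(a1) <- dim(hap)
  a2 <- c(1, 0, 1, 0)[hap]; dim(a2) <- dim(hap)
  list(gx = as.integer(rowSums(a1)), gy = as.integer(rowSums(a2)))
}

strong_model <- function() read_model_spec(example_model_path("strong_2locus"))
null_model <- function() read_model_spec(example_model_path("null_2locus"))
network_model <- function() read_model_spec(example_model_path("network_4locus_het"))

# One full simulate -> scan -> rank replicate on a shipped model.
run_replicate <- function(model, seed, n_case = 800, n_control = 800,
                          n_snps = 100, k = 100) {
  sim <- simulate_dataset(model, n_case, n_control, n_snps, seed = seed)
  scores <- scan_pairs(sim$genotypes, sim$phenotypes)
  ranked <- suppressWarnings(rank_pairs(scores, k = k))
  list(ranked = ranked, truth = sim$truth, scores = scores)
}
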