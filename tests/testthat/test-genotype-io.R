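test_that("ped/map genotypes are coded against the major allele", {
  dir <- withr::local_tempdir()
  # SNP1: genotypes A A, A G, G G across three samples; A is major -> wild
  # SNP2: all C C (monomorphic)
  a1 <- rbind(c("A", "A", "G"), c("C", "C", "C"))
  a2 <- rbind(c("A", "G", "G"), c("C", "C", "C"))
  f <- write_ped_map(dir, a1, a2, pheno = c("1", "1", "2"))
  dat <- read_plink_text(f$ped, f$map)
  expect_equal(unname(dat$genotypes$genotypes[1, ]), c(0L, 1L, 2L))
  expect_equal(dat$genotypes$snp_info$allele_wild, c("A", "C"))
  expect_true(dat$genotypes$snp_info$monomorphic[2])
  expect_equal(as.character(dat$phenotypes$status), c("control", "control", "case"))
})

test_that("PLINK missing alleles '0 0' become the missing code", {
  dir <- withr::local_tempdir()
  a1 <- rbind(c("A", "0", "A"))
  a2 <- rbind(c("A", "0", "G"))
  f <- write_ped_map(dir, a1, a2, pheno = c("1", "2", "2"))
  dat <- read_plink_text(f$ped, f$map)
  expect_equal(unname(dat$genotypes$genotypes[1, ]), c(0L, -9L, 1L))
})

test_that("malformed ped lines and bad phenotypes are rejected with line numbers", {
  dir <- withr::local_tempdir()
  writeLines("1 rs1 0 1000", file.path(dir, "m.map"))
  writeLines(c("F i1 0 0 1 1 A A", "F i2 0 0 1 2 A"), file.path(dir, "p.ped"))
  expect_error(read_plink_text(file.path(dir, "p.ped"), file.path(dir, "m.map")),
               "line 2")
  writeLines(c("F i1 0 0 1 0 A A"), file.path(dir, "p.ped"))
  expect_error(read_plink_text(file.path(dir, "p.ped"), file.path(dir, "m.map")),
               "phenotype")
})

test_that("TSV round-trip through ped reproduces codes exactly", {
  dir <- withr::local_tempdir()
  set.seed(41)
  n_snp <- 10; n_ind <- 12
  codes <- matrix(sample(c(0:2, -9L), n_snp * n_ind, replace = TRUE,
                         prob = c(0.4, 0.3, 0.2, 0.1)), n_snp, n_ind)
  # express codes as allele pairs (wild A / variant G), -9 as 0 0
  to1 <- ifelse(codes == -9L, "0", ifelse(codes >= 1, "G", "A"))
  to2 <- ifelse(codes == -9L, "0", ifelse(codes == 2, "G", "A"))
  pheno <- rep(c("1", "2"), length.out = n_ind)
  f <- write_ped_map(dir, to1, to2, pheno)
  dat <- read_plink_text(f$ped, f$map)
  # majority-wild can flip coding for variant-heavy SNPs; recompute expected
  exp_codes <- codes
  flip <- dat$genotypes$snp_info$allele_wild == "G"
  exp_codes[flip & codes != -9L] <- 2L - codes[flip & codes != -9L]
  expect_equal(unname(dat$genotypes$genotypes), unname(exp_codes))

  gt <- file.path(dir, "g.tsv"); lt <- file.path(dir, "l.tsv")
  write_genotype_tsv(dat$genotypes, gt)
  write_phenotype_tsv(dat$phenotypes, lt)
  back <- read_genotype_tsv(gt, lt)
  expect_identical(back$genotypes$genotypes, dat$genotypes$genotypes)
  expect_identical(back$genotypes$snp_info$allele_wild,
                   dat$genotypes$snp_info$allele_wild)
  expect_equal(back$phenotypes, dat$phenotypes)
})

test_that("genotype TSV parsing validates codes and rejects empty input", {
  dir <- withr::local_tempdir()
  gt <- file.path(dir, "g.tsv"); lt <- file.path(dir, "l.tsv")
  writeLines(c("sample_id\tstatus", "s1\tcase", "s2\tcontrol", "s3\tcase"), lt)
  writeLines(c("snp_id\tchrom\tpos\tallele_wild\tallele_variant\ts1\ts2\ts3",
               "rs1\t1\t100\tA\tG\t0\t1\t2"), gt)
  dat <- read_genotype_tsv(gt, lt)
  expect_equal(unname(dat$genotypes$genotypes[1, ]), c(0L, 1L, 2L))

  writeLines(c("snp_id\tchrom\tpos\tallele_wild\tallele_variant\ts1\ts2\ts3",
               "rs1\t1\t100\tA\tG\t0\t3\t2"), gt)
  expect_error(read_genotype_tsv(gt, lt), "rs1.*s2")

  writeLines("snp_id\tchrom\tpos\tallele_wild\tallele_variant\ts1\ts2\ts3", gt)
  expect_error(read_genotype_tsv(gt, lt), "no SNPs")
})

test_that("allele assignment follows majority rule with lexicographic ties", {
  out <- assign_alleles(list(c(A = 120, G = 80), c(C = 50, T = 50), c(A = 10)))
  expect_equal(out$allele_wild, c("A", "C", "A"))
  expect_equal(out$allele_variant, c("G", "T", NA))
  expect_equal(out$monomorphic, c(FALSE, FALSE, TRUE))
  expect_error(assign_alleles(list(c(A = 5, C = 5, G = 5))), "biallelic")
})

test_that("MAF filtering uses pooled allele counts with a strict threshold", {
  # one SNP with genotype counts (w,h,v) = (81,18,1): MAF = 20/200 = 0.10
  g <- matrix(c(rep(0L, 81), rep(1L, 18), rep(2L, 1)), nrow = 1)
  gm <- genotype_matrix(g, tibble::tibble(
    snp_id = "rs1", chrom = "1", pos = 1L,
    allele_wild = "A", allele_variant = "G"), sprintf("s%03d", 1:100))
  expect_equal(snp_maf(gm)$maf, 0.10)
  expect_equal(n_snps(filter_maf(gm, 0.05)), 1)
  expect_equal(n_snps(filter_maf(gm, 0.10)), 0)  # strict inequality

  mono <- genotype_matrix(matrix(0L, 1, 100), gm$snp_info,
                          sprintf("s%03d", 1:100))
  expect_equal(n_snps(filter_maf(mono, 0.01)), 0)
})

test_that("MAF filtering is idempotent and invariant to allele relabeling", {
  gm <- random_genotype_matrix(40, 60, miss_rate = 0.05, seed = 7)
  once <- filter_maf(gm, 0.05)
  twice <- filter_maf(once, 0.05)
  expect_identical(once$genotypes, twice$genotypes)

  # swapping w<->v at a SNP maps 0<->2, fixes 1 and -9, and preserves MAF
  swapped <- gm
  sw <- swapped$genotypes[3, ]
  sw[sw == 0L] <- 99L; sw[sw == 2L] <- 0L; sw[sw == 99L] <- 2L
  swapped$genotypes[3, ] <- sw
  expect_equal(snp_maf(swapped)$maf, snp_maf(gm)$maf)
})

test_that("region filtering honors flanks, half-open bounds, and a scan oracle", {
  mk <- function(pos) genotype_matrix(
    matrix(sample(0:2, length(pos) * 4, TRUE), length(pos), 4),
    tibble::tibble(snp_id = sprintf("rs%d", seq_along(pos)), chrom = "1",
                   pos = as.integer(pos), allele_wild = "A", allele_variant = "G"),
    sprintf("s%d", 1:4))
  rs <- region_set("1", 10000, 20000, flank = 10000)
  expect_equal(n_snps(filter_regions(mk(5000), rs)), 1)    # inside left flank
  expect_equal(n_snps(filter_regions(mk(30001), rs)), 0)   # past half-open end
  expect_equal(n_snps(filter_regions(mk(29999), rs)), 1)

  set.seed(11)
  pos <- sample.int(100000, 100)
  gm <- mk(pos)
  regs <- region_set(rep("1", 5), starts <- sample.int(80000, 5),
                     starts + sample.int(5000, 5), flank = 1000)
  kept <- filter_regions(gm, regs)
  # brute-force per-SNP linear scan
  s <- pmax(regs$start - 1000, 0); e <- regs$end + 1000
  want <- vapply(pos, function(p) any(p >= s & p < e), logical(1))
  expect_identical(kept$snp_info$snp_id, gm$snp_info$snp_id[want])
  # order-preserving subset
  expect_true(all(diff(match(kept$snp_info$snp_id, gm$snp_info$snp_id)) > 0))

  gm2 <- mk(5000); gm2$snp_info$chrom <- "2"
  expect_warning(filter_regions(gm2, rs), "chromosome")
})
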