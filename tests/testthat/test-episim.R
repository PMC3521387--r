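test_that("penetrance models validate their tables and mafs", {
  m1 <- penetrance_model(0.3, c(0.1, 0.2, 0.4), label = "single")
  expect_equal(m1$L, 1)
  expect_error(penetrance_model(c(0.2, 0.2), rep(0.1, 8)),
               "expected 9 entries")
  expect_error(penetrance_model(c(0.2, 0.2), c(rep(0.1, 8), 1.2)),
               "outside \\[0,1\\]")
  expect_error(penetrance_model(c(0.6, 0.2), rep(0.1, 9)), "mafs")
})

test_that("model spec files round-trip exactly", {
  m <- read_model_spec(example_model_path("strong_2locus"))
  expect_equal(m$L, 2)
  expect_equal(m$mafs, c(0.2, 0.2))
  expect_equal(m$table[c(1, 9)], c(0.25, 0.25))

  dir <- withr::local_tempdir()
  net <- read_model_spec(example_model_path("network_4locus_het"))
  comp <- compose_network_model(net)
  expect_length(comp$table, 81)
  p <- file.path(dir, "m.txt")
  write_model_spec(comp, p)
  back <- read_model_spec(p)
  expect_identical(back$table, comp$table)
  expect_identical(back$mafs, comp$mafs)

  writeLines(c("type: penetrance", "L: 2", "mafs: 0.2 0.2", "table:",
               paste(rep("0.1", 8), collapse = " ")), p)
  expect_error(read_model_spec(p), "expected 9 entries")
})

test_that("network composition matches exhaustive enumeration", {
  tabA <- runif(9) * 0.5
  tabB <- runif(9) * 0.5
  net <- interaction_network(
    tibble::tibble(node = c("A", "B", "C", "D"), maf = rep(0.25, 4)),
    list(list(from = "A", to = "B", table = tabA),
         list(from = "C", to = "D", table = tabB)),
    combine = "heterogeneity")
  comp <- compose_network_model(net)
  # enumeration oracle over all 81 genotype vectors, locus 1 slowest
  idx <- 0
  for (g1 in 0:2) for (g2 in 0:2) for (g3 in 0:2) for (g4 in 0:2) {
    idx <- idx + 1
    pA <- tabA[3 * g1 + g2 + 1]
    pB <- tabB[3 * g3 + g4 + 1]
    expect_equal(comp$table[idx], 1 - (1 - pA) * (1 - pB), tolerance = 1e-12)
  }

  # a single-edge network composes to that edge's own table
  net1 <- interaction_network(
    tibble::tibble(node = c("A", "B"), maf = c(0.2, 0.3)),
    list(list(from = "A", to = "B", table = tabA)))
  expect_equal(compose_network_model(net1)$table, tabA, tolerance = 1e-15)
  mult1 <- interaction_network(
    tibble::tibble(node = c("A", "B"), maf = c(0.2, 0.3)),
    list(list(from = "A", to = "B", table = tabA)), combine = "multiplicative")
  expect_equal(compose_network_model(mult1)$table, tabA / max(tabA))

  # an all-zero edge is the identity of the heterogeneity rule
  net0 <- interaction_network(
    tibble::tibble(node = c("A", "B", "C", "D"), maf = rep(0.25, 4)),
    list(list(from = "A", to = "B", table = tabA),
         list(from = "C", to = "D", table = rep(0, 9))))
  # composed index for (g1, g2, g3, g4), locus 1 slowest
  compA <- compose_network_model(net0)$table
  for (g1 in 0:2) for (g2 in 0:2) for (g3 in 0:2) for (g4 in 0:2) {
    expect_equal(compA[27 * g1 + 9 * g2 + 3 * g3 + g4 + 1],
                 tabA[3 * g1 + g2 + 1], tolerance = 1e-12)
  }

  expect_error(interaction_network(tibble::tibble(node = "A", maf = 0.2),
                                   list()), "at least one edge")
  expect_error(interaction_network(
    tibble::tibble(node = c("A", "B"), maf = c(0.2, 0.2)),
    list(list(from = "A", to = "Z", table = tabA))), "endpoint")
})

test_that("simulated datasets have exact quotas and are seed-reproducible", {
  sim <- simulate_dataset(strong_model(), 800, 800, 100, seed = 424)
  expect_equal(dim(sim$genotypes$genotypes), c(100, 1600))
  expect_equal(sum(sim$phenotypes$status == "case"), 800)
  expect_equal(sum(sim$phenotypes$status == "control"), 800)
  expect_length(sim$truth$disease_indices, 2)
  expect_equal(nrow(sim$truth$true_pairs), 1)

  again <- simulate_dataset(strong_model(), 800, 800, 100, seed = 424)
  expect_identical(sim$genotypes$genotypes, again$genotypes$genotypes)
  other <- simulate_dataset(strong_model(), 800, 800, 100, seed = 425)
  expect_false(identical(sim$genotypes$genotypes, other$genotypes$genotypes))

  expect_error(simulate_dataset(penetrance_model(0.2, c(0, 0, 0)), 10, 10, 5,
                                seed = 1), "cases unreachable")
  expect_error(simulate_dataset(penetrance_model(0.2, c(1, 1, 1)), 10, 10, 5,
                                seed = 1), "controls unreachable")
})

test_that("empirical prevalence matches the Hardy-Weinberg summation", {
  model <- strong_model()
  # independent oracle: explicit loop over the nine genotype cells
  q <- model$mafs
  hw <- function(g, qq) c((1 - qq)^2, 2 * qq * (1 - qq), qq^2)[g + 1]
  prev <- 0
  for (g1 in 0:2) for (g2 in 0:2) {
    prev <- prev + hw(g1, q[1]) * hw(g2, q[2]) * model$table[3 * g1 + g2 + 1]
  }
  expect_equal(analytic_prevalence(model), prev, tolerance = 1e-12)

  # measure prevalence from the simulator's own rejection stream at n ~ 50000
  sim <- simulate_dataset(model, n_case = 5000, n_control = 44000, n_snps = 2,
                          seed = 777)
  n <- sim$diagnostics$n_draws
  expect_gte(n, 44000)
  emp <- sim$diagnostics$n_case_draws / n
  mc_se <- sqrt(prev * (1 - prev) / n)
  expect_lt(abs(emp - prev), 3 * mc_se)
})

test_that("constant penetrance yields no genotype-disease association", {
  sim <- simulate_dataset(null_model(), 5000, 5000, 10, seed = 99)
  d <- sim$truth$disease_indices
  status <- sim$phenotypes$status
  for (locus in d) {
    g <- factor(sim$genotypes$genotypes[locus, ], levels = 0:2)
    p <- stats::chisq.test(table(g, status))$p.value
    expect_gt(p, 0.001)
  }
})

test_that("background SNPs follow Hardy-Weinberg proportions and carry no signal", {
  sim <- simulate_dataset(strong_model(), 2000, 2000, 20, seed = 55)
  bg <- setdiff(seq_len(20), sim$truth$disease_indices)
  # HWE goodness-of-fit at each background SNP from its realized allele freq
  pvals_hwe <- vapply(bg, function(s) {
    g <- sim$genotypes$genotypes[s, ]
    qhat <- mean(g) / 2
    expected <- 4000 * c((1 - qhat)^2, 2 * qhat * (1 - qhat), qhat^2)
    obs <- tabulate(g + 1, 3)
    stats::chisq.test(obs, p = expected / sum(expected))$p.value
  }, numeric(1))
  expect_gt(median(pvals_hwe), 0.05)

  pvals_assoc <- vapply(bg, function(s) {
    g <- factor(sim$genotypes$genotypes[s, ], levels = 0:2)
    suppressWarnings(stats::chisq.test(table(g, sim$phenotypes$status))$p.value)
  }, numeric(1))
  # under the null, association P-values are uniform
  expect_gt(median(pvals_assoc), 0.1)
})
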