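#' Multi-locus penetrance disease model
#'
#' A disease model over `L` biallelic loci: per-locus minor (variant) allele
#' frequencies and a table of `3^L` penetrances - the probability of disease
#' given the genotype vector. Table entries are in odometer order over
#' `{w, h, v}^L` with locus 1 varying slowest, i.e. for two loci:
#' ww, wh, wv, hw, hh, hv, vw, vh, vv.
#'
#' @param mafs Numeric vector of per-locus variant-allele frequencies in
#'   `(0, 0.5]`.
#' @param table Numeric vector of `3^length(mafs)` penetrances in `[0, 1]`.
#' @param label Free-text model name.
#' @param h2 Optional nominal heritability annotation (not used in sampling).
#' @return An object of class `penetrance_model`.
#' @export
#' @examples
#' # two-locus model: elevated risk when both loci are the same homozygote
#' m <- penetrance_model(
#'   mafs = c(0.2, 0.2),
#'   table = c(0.25, 0.02, 0.02, 0.02, 0.02, 0.02, 0.02, 0.02, 0.25),
#'   label = "concordant-homozygote"
#' )
#' analytic_prevalence(m)
penetrance_model <- function(mafs, table, label = "", h2 = NULL) {
  L <- length(mafs)
  if (L < 1) stop("need at least one locus", call. = FALSE)
  if (any(mafs <= 0 | mafs > 0.5)) {
    stop("mafs must lie in (0, 0.5]", call. = FALSE)
  }
  if (length(table) != 3^L) {
    stop("expected ", 3^L, " entries in penetrance table, got ",
         length(table), call. = FALSE)
  }
  bad <- which(table < 0 | table > 1 | is.na(table))
  if (length(bad) > 0) {
    stop("penetrance outside [0,1] at cell ", bad[1], " (",
         genotype_cell_label(bad[1], L), ")", call. = FALSE)
  }
  structure(list(L = L, mafs = as.numeric(mafs), table = as.numeric(table),
                 label = label, h2 = h2),
            class = "penetrance_model")
}

# cell index (1-based, odometer order, locus 1 slowest) -> label like "wv"
genotype_cell_label <- function(idx, L) {
  g <- integer(L)
  r <- idx - 1
  for (l in L:1) {
    g[l] <- r %% 3
    r <- r %/% 3
  }
  paste(c("w", "h", "v")[g + 1], collapse = "")
}

# genotype matrix (L x n, codes 0/1/2) -> penetrance vector
penetrance_at <- function(model, geno) {
  L <- model$L
  idx <- rep(0, ncol(geno))
  for (l in seq_len(L)) idx <- idx * 3 + geno[l, ]
  model$table[idx + 1]
}

#' @export
print.penetrance_model <- function(x, ...) {
  cat("<penetrance_model> ", x$L, " locus/loci",
      if (nzchar(x$label)) paste0(" '", x$label, "'"), "\n", sep = "")
  cat("  mafs: ", paste(format(x$mafs), collapse = ", "), "\n", sep = "")
  cat("  penetrance range: [", min(x$table), ", ", max(x$table), "]\n", sep = "")
  invisible(x)
}

#' Population disease prevalence implied by a penetrance model
#'
#' Sums penetrance times the Hardy-Weinberg probability of each of the `3^L`
#' genotype vectors, with per-locus genotype probabilities
#' `((1-q)^2, 2q(1-q), q^2)` at variant-allele frequency `q`.
#'
#' @param model A [penetrance_model()].
#' @return Expected disease prevalence in `[0, 1]`.
#' @export
analytic_prevalence <- function(model) {
  probs <- lapply(model$mafs, function(q) c((1 - q)^2, 2 * q * (1 - q), q^2))
  # rows enumerate genotype vectors in odometer order, locus 1 slowest,
  # matching the penetrance table layout
  grid <- as.matrix(expand.grid(rev(replicate(model$L, 0:2, simplify = FALSE))))
  grid <- grid[, rev(seq_len(model$L)), drop = FALSE]
  hwe <- vapply(seq_len(nrow(grid)), function(r) {
    prod(vapply(seq_len(model$L),
                function(l) probs[[l]][grid[r, l] + 1], numeric(1)))
  }, numeric(1))
  sum(hwe * model$table)
}

#' Pairwise interaction network disease model
#'
#' Nodes are disease loci with variant-allele frequencies; each edge carries a
#' two-locus penetrance table (9 entries, odometer order, `from` locus
#' slowest). [compose_network_model()] combines the edges into one
#' `3^L`-entry table.
#'
#' @param nodes Data frame with columns `node` (name) and `maf`.
#' @param edges List of edges, each a list with `from`, `to` (node names) and
#'   `table` (9 penetrances).
#' @param combine `"heterogeneity"` (default) or `"multiplicative"`.
#' @return An object of class `interaction_network`.
#' @export
interaction_network <- function(nodes, edges,
                                combine = c("heterogeneity", "multiplicative")) {
  combine <- match.arg(combine)
  nodes <- tibble::as_tibble(nodes)
  stopifnot(all(c("node", "maf") %in% names(nodes)))
  if (length(edges) < 1) stop("network needs at least one edge", call. = FALSE)
  for (e in edges) {
    if (!all(c(e$from, e$to) %in% nodes$node)) {
      stop("edge endpoint not among declared nodes: ", e$from, "-", e$to,
           call. = FALSE)
    }
    if (length(e$table) != 9) {
      stop("edge ", e$from, "-", e$to, ": expected 9 entries, got ",
           length(e$table), call. = FALSE)
    }
    if (any(e$table < 0 | e$table > 1)) {
      stop("edge ", e$from, "-", e$to, ": penetrance outside [0,1]",
           call. = FALSE)
    }
  }
  structure(list(nodes = nodes, edges = edges, combine = combine),
            class = "interaction_network")
}

#' Compose a network of pairwise penetrances into one multi-locus model
#'
#' Under the heterogeneity rule each edge is an independent disease route:
#' overall penetrance is `1 - prod(1 - pen_edge)`. Under the multiplicative
#' rule penetrances multiply and are rescaled into `[0, 1]` by the maximum
#' product. Node order in the network defines locus order in the composed
#' table.
#'
#' @param net An [interaction_network()] with at most 6 nodes (table size
#'   `3^L`).
#' @return A [penetrance_model()] over all network nodes.
#' @export
compose_network_model <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  L <- nrow(net$nodes)
  if (L > 6) stop("composed table limited to 6 loci", call. = FALSE)
  # enumerate genotype vectors, locus 1 slowest
  geno <- t(as.matrix(expand.grid(rev(replicate(L, 0:2, simplify = FALSE)))))
  geno <- geno[rev(seq_len(L)), , drop = FALSE]   # row l = locus l
  rownames(geno) <- net$nodes$node
  pens <- vapply(net$edges, function(e) {
    idx <- 3 * geno[e$from, ] + geno[e$to, ] + 1
    e$table[idx]
  }, numeric(ncol(geno)))
  pens <- matrix(pens, ncol = length(net$edges))
  table <- if (net$combine == "heterogeneity") {
    1 - apply(1 - pens, 1, prod)
  } else {
    pr <- apply(pens, 1, prod)
    if (max(pr) > 0) pr / max(pr) else pr
  }
  penetrance_model(net$nodes$maf, table,
                   label = paste0("composed_", net$combine, "_", L, "loci"))
}

#' Simulate a case/control genotype dataset from a disease model
#'
#' Individuals are drawn as independent genotype vectors: every locus is
#' sampled under Hardy-Weinberg equilibrium from its variant-allele frequency
#' (genotype probabilities `(1-q)^2, 2q(1-q), q^2`), background SNP
#' frequencies drawn once, uniformly over `background_maf_range`. Disease
#' status is Bernoulli with probability equal to the model's penetrance at the
#' individual's disease-locus genotypes. Sampling continues, discarding the
#' excess class, until exactly `n_case` cases and `n_control` controls are
#' collected.
#'
#' @param model A [penetrance_model()] or [interaction_network()] (composed
#'   internally with its own combine rule).
#' @param n_case,n_control Required group sizes.
#' @param n_snps Total SNPs including the embedded disease loci.
#' @param seed Integer seed; the full output is reproducible from it.
#' @param background_maf_range Range for background variant-allele
#'   frequencies (default `c(0.05, 0.5)`, matching a MAF>0.05 filter regime).
#' @param disease_positions Indices at which the model loci are embedded;
#'   default: evenly spaced across the SNP panel.
#' @param max_draws Rejection-sampling budget of individual draws before
#'   erroring on pathological models (default 1e8).
#' @return A list with `genotypes` (a [genotype_matrix()], cases first),
#'   `phenotypes` (tibble), `truth` - a list with `disease_indices`,
#'   `true_pairs` (tibble `i`, `j`), `scenario`, `model_label`, `seed` - and
#'   `diagnostics` with the rejection-stream totals `n_draws` and
#'   `n_case_draws` (their ratio estimates the model's prevalence).
#' @export
simulate_dataset <- function(model, n_case, n_control, n_snps, seed,
                             background_maf_range = c(0.05, 0.5),
                             disease_positions = NULL, max_draws = 1e8) {
  stopifnot(n_case >= 1, n_control >= 1)
  net <- NULL
  if (inherits(model, "interaction_network")) {
    net <- model
    model <- compose_network_model(model)
  }
  L <- model$L
  if (n_snps < L) stop("n_snps must be at least the number of disease loci",
                       call. = FALSE)
  if (all(model$table == 0)) {
    stop("all penetrances are 0: cases unreachable", call. = FALSE)
  }
  if (all(model$table == 1)) {
    stop("all penetrances are 1: controls unreachable", call. = FALSE)
  }
  if (is.null(disease_positions)) {
    disease_positions <- unique(round(seq(1, n_snps, length.out = L + 2)))[-c(1, L + 2)]
    if (length(disease_positions) < L) {
      disease_positions <- seq_len(L)
    } else {
      disease_positions <- disease_positions[seq_len(L)]
    }
  }
  stopifnot(length(disease_positions) == L,
            !anyDuplicated(disease_positions),
            all(disease_positions >= 1 & disease_positions <= n_snps))

  set.seed(seed)
  mafs <- stats::runif(n_snps, background_maf_range[1], background_maf_range[2])
  mafs[disease_positions] <- model$mafs

  acc_case <- list(); acc_ctrl <- list()
  got_case <- 0; got_ctrl <- 0; drawn <- 0; case_draws <- 0
  batch <- max(1000, min(20000, 4 * (n_case + n_control)))
  while (got_case < n_case || got_ctrl < n_control) {
    if (drawn >= max_draws) {
      stop("draw budget exhausted before filling case/control quotas",
           call. = FALSE)
    }
    nb <- as.integer(min(batch, max_draws - drawn))
    G <- matrix(stats::rbinom(n_snps * nb, 2, rep(mafs, nb)),
                nrow = n_snps, ncol = nb)
    drawn <- drawn + nb
    pen <- penetrance_at(model, G[disease_positions, , drop = FALSE])
    is_case <- stats::runif(nb) < pen
    case_draws <- case_draws + sum(is_case)
    if (got_case < n_case && any(is_case)) {
      acc_case[[length(acc_case) + 1]] <- G[, is_case, drop = FALSE]
      got_case <- got_case + sum(is_case)
    }
    if (got_ctrl < n_control && any(!is_case)) {
      acc_ctrl[[length(acc_ctrl) + 1]] <- G[, !is_case, drop = FALSE]
      got_ctrl <- got_ctrl + sum(!is_case)
    }
  }
  Gc <- do.call(cbind, acc_case)[, seq_len(n_case), drop = FALSE]
  Gt <- do.call(cbind, acc_ctrl)[, seq_len(n_control), drop = FALSE]
  G <- cbind(Gc, Gt)
  storage.mode(G) <- "integer"

  ids <- sprintf("ind%05d", seq_len(n_case + n_control))
  status <- c(rep("case", n_case), rep("control", n_control))
  snp_info <- tibble::tibble(
    snp_id = sprintf("snp%04d", seq_len(n_snps)),
    chrom = "1", pos = as.integer(seq_len(n_snps) * 1000L),
    allele_wild = "A", allele_variant = "B", monomorphic = FALSE
  )
  truth <- list(
    disease_indices = as.integer(sort(disease_positions)),
    true_pairs = truth_pairs(model, net, disease_positions),
    scenario = if (!is.null(net)) "higher_order"
               else if (L == 2) "single_pair" else "multi_locus",
    model_label = model$label,
    seed = as.integer(seed)
  )
  list(
    genotypes = genotype_matrix(G, snp_info, ids),
    phenotypes = phenotype_labels(ids, status),
    truth = truth,
    diagnostics = list(n_draws = drawn, n_case_draws = case_draws)
  )
}

truth_pairs <- function(model, net, disease_positions) {
  if (!is.null(net)) {
    pos <- stats::setNames(disease_positions, net$nodes$node)
    pairs <- purrr::map(net$edges, function(e) {
      sort(c(pos[[e$from]], pos[[e$to]]))
    })
    tibble::tibble(i = vapply(pairs, `[`, numeric(1), 1),
                   j = vapply(pairs, `[`, numeric(1), 2))
  } else if (model$L >= 2) {
    cmb <- utils::combn(sort(disease_positions), 2)
    tibble::tibble(i = cmb[1, ], j = cmb[2, ])
  } else {
    tibble::tibble(i = integer(0), j = integer(0))
  }
}

#' Read / write a disease-model specification file
#'
#' Plain-text format. Lines beginning `#` are comments. A penetrance-table
#' spec has key-value header lines (`type: penetrance`, `L:`, `mafs:`,
#' `label:`, `h2:`), then a `table:` line followed by `3^L` whitespace- or
#' newline-separated penetrances in odometer order over `{w, h, v}^L`, locus 1
#' slowest. A network spec (`type: network`) has a `combine:` line, `node:`
#' lines (`node: NAME MAF`) and `edge:` lines (`edge: FROM TO p1 ... p9`).
#'
#' @param path File path.
#' @return A [penetrance_model()] or [interaction_network()].
#' @export
read_model_spec <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- function(key) {
    hit <- grep(paste0("^", key, ":"), lines, value = TRUE)
    if (length(hit) == 0) return(NULL)
    trimws(sub(paste0("^", key, ":"), "", hit[1]))
  }
  type <- kv("type") %||% "penetrance"
  if (type == "network") {
    combine <- kv("combine") %||% "heterogeneity"
    node_lines <- grep("^node:", lines, value = TRUE)
    nodes <- purrr::map_dfr(node_lines, function(ln) {
      f <- strsplit(trimws(sub("^node:", "", ln)), "[ \t]+")[[1]]
      tibble::tibble(node = f[1], maf = as.numeric(f[2]))
    })
    edge_lines <- grep("^edge:", lines, value = TRUE)
    edges <- purrr::map(edge_lines, function(ln) {
      f <- strsplit(trimws(sub("^edge:", "", ln)), "[ \t]+")[[1]]
      list(from = f[1], to = f[2], table = as.numeric(f[-(1:2)]))
    })
    return(interaction_network(nodes, edges, combine = combine))
  }
  L <- as.integer(kv("L"))
  mafs <- as.numeric(strsplit(kv("mafs"), "[ \t]+")[[1]])
  if (!is.na(L) && length(mafs) != L) {
    stop("header says L=", L, " but ", length(mafs), " mafs given", call. = FALSE)
  }
  ti <- grep("^table:", lines)
  if (length(ti) == 0) stop("no table: section in model spec", call. = FALSE)
  tail_first <- trimws(sub("^table:", "", lines[ti[1]]))
  body <- c(tail_first, if (ti[1] < length(lines)) lines[(ti[1] + 1):length(lines)])
  body <- body[!grepl("^[a-z_]+:", body)]
  tokens <- strsplit(paste(body, collapse = " "), "[ \t]+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  table <- as.numeric(tokens)
  if (length(table) != 3^length(mafs)) {
    stop("expected ", 3^length(mafs), " entries in penetrance table, got ",
         length(table), call. = FALSE)
  }
  h2 <- kv("h2")
  penetrance_model(mafs, table, label = kv("label") %||% "",
                   h2 = if (!is.null(h2)) as.numeric(h2) else NULL)
}

#' @rdname read_model_spec
#' @param model A [penetrance_model()] to write.
#' @export
write_model_spec <- function(model, path) {
  stopifnot(inherits(model, "penetrance_model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "type: penetrance",
    paste0("L: ", model$L),
    paste0("mafs: ", paste(format(model$mafs, digits = 15), collapse = " ")),
    paste0("label: ", model$label),
    if (!is.null(model$h2)) paste0("h2: ", model$h2),
    "table:",
    vapply(split(model$table, ceiling(seq_along(model$table) / 9)),
           function(x) paste(format(x, digits = 17), collapse = " "),
           character(1))
  ), con)
  invisible(path)
}

#' Write / read the simulation truth sidecar (JSON)
#'
#' @param truth The `truth` element returned by [simulate_dataset()].
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  truth$disease_indices <- as.integer(truth$disease_indices)
  truth$true_pairs <- tibble::as_tibble(truth$true_pairs)
  truth
}

#' Path to a disease-model spec shipped with the package
#'
#' Shipped specs (reconstructed examples of the model families commonly used
#' in epistasis-simulation benchmarks; see file comments):
#' `strong_2locus`, `marginal_2locus`, `null_2locus`, `network_4locus_het`.
#'
#' @param name Spec name without extension.
#' @return Absolute file path.
#' @export
#' @examples
#' read_model_spec(example_model_path("strong_2locus"))
example_model_path <- function(name) {
  p <- system.file("extdata", "models", paste0(name, ".txt"),
                   package = "epicontrast")
  if (p == "") stop("no shipped model named '", name, "'", call. = FALSE)
  p
}
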