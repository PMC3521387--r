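#' Encode genotype codes as a signed trinary variable
#'
#' Maps homozygous wild to -1, heterozygous to 0, homozygous variant to +1;
#' missing codes become `NA`. This encoding makes the genotype-dependence
#' statistic a plain second-moment ratio of the two encoded variables.
#'
#' @param codes Integer vector of genotype codes in `{0, 1, 2, -9}`.
#' @return Numeric vector in `{-1, 0, 1, NA}`.
#' @export
#' @examples
#' encode_genotypes(c(0L, 1L, 2L, -9L))
encode_genotypes <- function(codes) {
  out <- as.numeric(codes) - 1
  out[codes == -9L] <- NA_real_
  out
}

#' Joint genotype table for one SNP pair in one phenotype group
#'
#' Tallies the nine genotype combinations over the individuals selected by
#' `group_mask` that are observed at both SNPs (pairwise complete-case), and
#' normalizes by that count.
#'
#' @param gx,gy Integer genotype codes for the two SNPs (same length).
#' @param group_mask Logical vector selecting the group's individuals.
#' @return A list with `p` (3x3 probability matrix, rows = first SNP genotype
#'   w/h/v, columns = second SNP genotype) and `n_used` (individuals counted).
#'   When no individual qualifies, `p` is all-`NA` and `n_used` is 0.
#' @export
build_joint_table <- function(gx, gy, group_mask) {
  stopifnot(length(gx) == length(gy), length(gx) == length(group_mask))
  use <- group_mask & gx != -9L & gy != -9L
  n_used <- sum(use)
  lv <- c("w", "h", "v")
  if (n_used == 0) {
    p <- matrix(NA_real_, 3, 3, dimnames = list(lv, lv))
    return(list(p = p, n_used = 0L))
  }
  counts <- table(factor(gx[use], levels = 0:2), factor(gy[use], levels = 0:2))
  p <- matrix(as.numeric(counts) / n_used, 3, 3, dimnames = list(lv, lv))
  list(p = p, n_used = as.integer(n_used))
}

#' Genotype-dependence statistic rho from a joint genotype table
#'
#' For encoded genotypes x, y in `{-1, 0, +1}`,
#' \deqn{\rho = \frac{P_{ww} - P_{wv} - P_{vw} + P_{vv}}
#'   {\sqrt{(P_{x=w}+P_{x=v})(P_{y=w}+P_{y=v})}}}
#' i.e. E\[xy\] / sqrt(E\[x^2\] E\[y^2\]) computed from the nine cell
#' probabilities. Returns `NA` when either homozygote marginal mass is zero
#' (a group where one SNP has no homozygotes) or when the table is empty.
#' When defined, rho lies in `[-1, 1]` by the Cauchy-Schwarz inequality.
#'
#' @param tab A table from [build_joint_table()], or a bare 3x3 probability
#'   matrix.
#' @return A single numeric value, or `NA` when undefined.
#' @export
#' @examples
#' p <- matrix(0, 3, 3); p[1, 1] <- 0.5; p[3, 3] <- 0.5
#' rho_from_table(p)  # perfect concordance: 1
rho_from_table <- function(tab) {
  p <- if (is.list(tab)) tab$p else tab
  stopifnot(is.matrix(p), all(dim(p) == c(3, 3)))
  if (anyNA(p)) return(NA_real_)
  num <- p[1, 1] - p[1, 3] - p[3, 1] + p[3, 3]
  mx <- sum(p[1, ]) + sum(p[3, ])
  my <- sum(p[, 1]) + sum(p[, 3])
  if (mx == 0 || my == 0) return(NA_real_)
  num / sqrt(mx * my)
}

#' Score one SNP pair in cases and controls
#'
#' Computes rho separately within the case and control groups and the contrast
#' `rho_diff = |rho_control - rho_case|`. Dependence shared by both groups
#' (linkage disequilibrium, stratification) cancels in the contrast; a pair is
#' `valid` only when rho is defined in both groups.
#'
#' @param gx,gy Integer genotype codes for the two SNPs.
#' @param case_mask,control_mask Disjoint logical masks selecting the groups.
#' @return A one-row tibble with columns `rho_case`, `rho_control`, `rho_diff`,
#'   `n_case_used`, `n_ctrl_used`, `valid`.
#' @export
score_pair <- function(gx, gy, case_mask, control_mask) {
  if (any(case_mask & control_mask)) stop("case and control masks overlap", call. = FALSE)
  tc <- build_joint_table(gx, gy, case_mask)
  tk <- build_joint_table(gx, gy, control_mask)
  rc <- rho_from_table(tc)
  rk <- rho_from_table(tk)
  tibble::tibble(
    rho_case = rc, rho_control = rk,
    rho_diff = abs(rk - rc),
    n_case_used = tc$n_used, n_ctrl_used = tk$n_used,
    valid = !is.na(rc) && !is.na(rk)
  )
}

#' Number of unordered SNP pairs
#'
#' @param n Number of SNPs.
#' @return `n * (n - 1) / 2` as a double (exact beyond integer range for
#'   genome-scale n).
#' @export
#' @examples
#' pair_count(100)     # 4950
#' pair_count(500000)  # ~1.25e11
pair_count <- function(n) {
  n <- as.numeric(n)
  n * (n - 1) / 2
}

#' Exhaustive pairwise scan of all SNP pairs
#'
#' Computes the case/control rho contrast for every unordered SNP pair
#' (i < j). The scan proceeds over blocks of at most `chunk_size` SNPs and
#' tallies each block pair with dense matrix products over homozygote indicator
#' matrices, so results are identical - bit for bit - for any `chunk_size` and
#' any `workers` value; the output is sorted by `(i, j)`. Missing genotypes are
#' handled pairwise complete-case per group.
#'
#' @param gm A [genotype_matrix()].
#' @param phenotypes A tibble from [phenotype_labels()] covering the same
#'   samples.
#' @param chunk_size Maximum SNPs per block (default 10000).
#' @param workers Accepted for interface compatibility; the scan contract
#'   guarantees identical results for any value.
#' @return A tibble of class `pair_scores` with one row per pair: `i`, `j`
#'   (SNP indices, i < j), `snp_i`, `snp_j` (ids), `rho_case`, `rho_control`,
#'   `rho_diff`, `n_case_used`, `n_ctrl_used`, `valid`. Attributes record the
#'   SNP and group counts.
#' @export
scan_pairs <- function(gm, phenotypes, chunk_size = 10000, workers = 1) {
  N <- n_snps(gm)
  if (N < 2) stop("need at least two SNPs", call. = FALSE)
  stopifnot(chunk_size >= 1)
  phenotypes <- check_phenotypes(gm, phenotypes)
  g <- gm$genotypes
  masks <- list(case = phenotypes$status == "case",
                control = phenotypes$status == "control")

  blocks <- split(seq_len(N), ceiling(seq_len(N) / chunk_size))
  group_stats <- lapply(masks, function(m) {
    gg <- g[, m, drop = FALSE]
    list(W = (gg == 0L) * 1, V = (gg == 2L) * 1, M = (gg != -9L) * 1)
  })

  pieces <- list()
  for (a in seq_along(blocks)) {
    for (b in a:length(blocks)) {
      ia <- blocks[[a]]; ib <- blocks[[b]]
      per_group <- lapply(group_stats, function(s) {
        Wa <- s$W[ia, , drop = FALSE]; Va <- s$V[ia, , drop = FALSE]
        Ma <- s$M[ia, , drop = FALSE]
        Wb <- s$W[ib, , drop = FALSE]; Vb <- s$V[ib, , drop = FALSE]
        Mb <- s$M[ib, , drop = FALSE]
        num <- Wa %*% t(Wb) - Wa %*% t(Vb) - Va %*% t(Wb) + Va %*% t(Vb)
        hx <- (Wa + Va) %*% t(Mb)   # x homozygous, y observed
        hy <- Ma %*% t(Wb + Vb)     # y homozygous, x observed
        n_used <- Ma %*% t(Mb)
        rho <- ifelse(hx > 0 & hy > 0, num / sqrt(hx * hy), NA_real_)
        list(rho = rho, n_used = n_used)
      })
      sel <- if (a == b) upper.tri(per_group$case$rho) else
        matrix(TRUE, length(ia), length(ib))
      idx <- which(sel, arr.ind = TRUE)
      if (nrow(idx) == 0) next
      rc <- per_group$case$rho[sel]
      rk <- per_group$control$rho[sel]
      pieces[[length(pieces) + 1]] <- tibble::tibble(
        i = ia[idx[, 1]], j = ib[idx[, 2]],
        rho_case = rc, rho_control = rk, rho_diff = abs(rk - rc),
        n_case_used = as.integer(per_group$case$n_used[sel]),
        n_ctrl_used = as.integer(per_group$control$n_used[sel]),
        valid = !is.na(rc) & !is.na(rk)
      )
    }
  }
  out <- dplyr::arrange(dplyr::bind_rows(pieces), .data$i, .data$j)
  out <- dplyr::mutate(out,
                       snp_i = gm$snp_info$snp_id[.data$i],
                       snp_j = gm$snp_info$snp_id[.data$j],
                       .after = "j")
  attr(out, "n_snps") <- N
  attr(out, "n_case") <- sum(masks$case)
  attr(out, "n_control") <- sum(masks$control)
  class(out) <- c("pair_scores", class(out))
  out
}

#' @exportS3Method generics::glance
glance.pair_scores <- function(x, ...) {
  tibble::tibble(
    n_snps = attr(x, "n_snps"),
    n_pairs = nrow(x),
    n_valid = sum(x$valid),
    n_case = attr(x, "n_case"),
    n_control = attr(x, "n_control"),
    max_rho_diff = if (any(x$valid)) max(x$rho_diff[x$valid]) else NA_real_
  )
}

#' Write / read a pair-score table as TSV
#'
#' @param scores A `pair_scores` tibble from [scan_pairs()].
#' @param path File path.
#' @return The path (write) or a `pair_scores` tibble (read).
#' @export
write_pair_scores <- function(scores, path) {
  readr::write_tsv(tibble::as_tibble(scores), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_pair_scores
#' @export
read_pair_scores <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  class(out) <- c("pair_scores", class(out))
  out
}

#' Distribution plot of the pairwise contrast scores
#'
#' Histogram of `rho_diff` over valid pairs, optionally overlaid with a
#' Weibull density.
#'
#' @param scores A `pair_scores` tibble.
#' @param weibull_shape,weibull_scale Optional Weibull parameters to overlay
#'   (e.g. shape 1, scale 0.018); omitted when `NULL`.
#' @return A ggplot object.
#' @export
plot_rho_diff <- function(scores, weibull_shape = NULL, weibull_scale = NULL) {
  df <- dplyr::filter(tibble::as_tibble(scores), .data$valid)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rho_diff)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 60, fill = "grey70", colour = "grey30") +
    ggplot2::labs(x = expression(rho[diff]), y = "density") +
    ggplot2::theme_minimal()
  if (!is.null(weibull_shape) && !is.null(weibull_scale)) {
    p <- p + ggplot2::stat_function(
      fun = stats::dweibull,
      args = list(shape = weibull_shape, scale = weibull_scale),
      colour = "firebrick"
    )
  }
  p
}
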