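#' Weibull upper-tail P-value for a contrast score
#'
#' The genome-wide empirical distribution of the pairwise contrast score is
#' well described by a Weibull distribution; with the default shape 1 and
#' scale 0.018 this function reproduces the published lookup table of tail
#' probabilities.
#'
#' Two evaluation modes are provided. The default computes the complement of
#' the CDF, `1 - pweibull(score, shape, scale)`, in double precision; near the
#' top of the distribution the CDF rounds to within a few ulps of 1, so the
#' complement is quantized to multiples of the unit roundoff (2.2204e-16) and
#' underflows to 0 for scores beyond ~0.65 at the default parameters - the
#' behavior of a lookup table computed via the CDF. With `exact = TRUE` the
#' survival function `exp(-(score/scale)^shape)` is evaluated directly, which
#' is the numerically preferable form for downstream arithmetic on very small
#' tail probabilities.
#'
#' @param score Non-negative contrast score(s) (`rho_diff`).
#' @param shape,scale Weibull parameters; defaults 1 and 0.018.
#' @param exact If `TRUE`, evaluate the survival function directly.
#' @return Upper-tail probability, same length as `score`.
#' @export
#' @examples
#' weibull_tail_pvalue(c(0.05, 0.30, 0.65))
#' weibull_tail_pvalue(0.65, exact = TRUE)
weibull_tail_pvalue <- function(score, shape = 1, scale = 0.018, exact = FALSE) {
  stopifnot(shape > 0, scale > 0)
  if (any(score < 0)) stop("score must be non-negative", call. = FALSE)
  if (exact) {
    stats::pweibull(score, shape = shape, scale = scale, lower.tail = FALSE)
  } else {
    1 - stats::pweibull(score, shape = shape, scale = scale)
  }
}

#' Rank SNP pairs by contrast score and attach tail P-values
#'
#' Invalid pairs (rho undefined in either group) are excluded. Pairs are
#' ordered by decreasing `rho_diff`, ties broken by ascending `(i, j)`; the
#' top `k` are returned with 1-based ranks and Weibull tail P-values. Ranking,
#' not a P-value cutoff, is the intended selection interface: the empirical
#' score distribution is heavy-tailed and fixed cutoffs admit very large
#' numbers of pairs.
#'
#' @param scores A `pair_scores` tibble from [scan_pairs()].
#' @param k Number of top pairs to keep (default 1000). If fewer valid pairs
#'   exist, all are returned with a warning.
#' @param shape,scale,exact Passed to [weibull_tail_pvalue()].
#' @return A tibble of class `ranked_pairs` with a leading `rank` column and a
#'   `p_value` column appended to the pair-score columns.
#' @export
rank_pairs <- function(scores, k = 1000, shape = 1, scale = 0.018,
                       exact = FALSE) {
  stopifnot(k >= 1)
  df <- dplyr::filter(tibble::as_tibble(scores), .data$valid)
  if (nrow(df) == 0) stop("no valid pairs to rank", call. = FALSE)
  if (nrow(df) < k) {
    warning("only ", nrow(df), " valid pairs; returning all", call. = FALSE)
    k <- nrow(df)
  }
  df <- dplyr::arrange(df, dplyr::desc(.data$rho_diff), .data$i, .data$j)
  df <- df[seq_len(k), , drop = FALSE]
  out <- dplyr::mutate(
    df,
    rank = dplyr::row_number(),
    p_value = weibull_tail_pvalue(.data$rho_diff, shape = shape,
                                  scale = scale, exact = exact),
    .before = 1
  )
  # rank was placed first, keep p_value after scores
  out <- dplyr::relocate(out, "p_value", .after = dplyr::last_col())
  attr(out, "k_requested") <- k
  attr(out, "pvalue_model") <- list(shape = shape, scale = scale, exact = exact)
  class(out) <- c("ranked_pairs", class(out))
  out
}

#' @exportS3Method generics::tidy
tidy.ranked_pairs <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Summary of a ranked top-K list
#'
#' Reports the 1st and K-th contrast scores with their P-values, and the mean
#' and standard deviation (sample, n-1 denominator) of `rho_diff` over the
#' list.
#'
#' @param ranked A `ranked_pairs` tibble.
#' @return A one-row tibble: `k`, `rho_diff_first`, `p_first`, `rho_diff_kth`,
#'   `p_kth`, `rho_diff_mean`, `rho_diff_sd`.
#' @export
summarize_topk <- function(ranked) {
  if (nrow(ranked) == 0) stop("empty ranking", call. = FALSE)
  kk <- nrow(ranked)
  tibble::tibble(
    k = kk,
    rho_diff_first = ranked$rho_diff[1],
    p_first = ranked$p_value[1],
    rho_diff_kth = ranked$rho_diff[kk],
    p_kth = ranked$p_value[kk],
    rho_diff_mean = mean(ranked$rho_diff),
    rho_diff_sd = if (kk > 1) stats::sd(ranked$rho_diff) else 0
  )
}

#' @exportS3Method generics::glance
glance.ranked_pairs <- function(x, ...) summarize_topk(x)

#' Hub SNPs among the top-ranked pairs
#'
#' A hub SNP is one that recurs across many top-ranked pairs. Counts each
#' SNP's occurrences over the ranked list (every pair contributes its two
#' endpoints, so degrees sum to twice the number of pairs) and reports SNPs
#' with degree at least `min_degree`, sorted by decreasing degree, ties by SNP
#' index.
#'
#' @param ranked A `ranked_pairs` tibble.
#' @param min_degree Minimum occurrences to report (default 1).
#' @return A tibble with columns `snp_index`, `snp_id`, `degree`.
#' @export
detect_hubs <- function(ranked, min_degree = 1) {
  if (nrow(ranked) == 0) stop("empty ranking", call. = FALSE)
  long <- tibble::tibble(
    snp_index = c(ranked$i, ranked$j),
    snp_id = c(ranked$snp_i, ranked$snp_j)
  )
  out <- dplyr::summarise(dplyr::group_by(long, .data$snp_index, .data$snp_id),
                          degree = dplyr::n(), .groups = "drop")
  out <- dplyr::arrange(out, dplyr::desc(.data$degree), .data$snp_index)
  dplyr::filter(out, .data$degree >= min_degree)
}

#' Write / read a ranked-pair table as TSV
#'
#' @param ranked A `ranked_pairs` tibble.
#' @param path File path.
#' @export
write_ranked_pairs <- function(ranked, path) {
  readr::write_tsv(tibble::as_tibble(ranked), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_ranked_pairs
#' @export
read_ranked_pairs <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  class(out) <- c("ranked_pairs", class(out))
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.ranked_pairs <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$rank, y = .data$rho_diff)) +
    ggplot2::geom_point(size = 0.8, colour = "steelblue") +
    ggplot2::labs(x = "rank", y = expression(rho[diff])) +
    ggplot2::theme_minimal()
}
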