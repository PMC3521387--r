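#' Accuracy rule: single interacting pair
#'
#' A replicate counts as correct when the rank-1 pair is exactly the true
#' disease pair (unordered comparison); a rank-1 pair sharing only one SNP
#' with the truth is incorrect.
#'
#' @param ranked A `ranked_pairs` tibble.
#' @param truth A truth record from [simulate_dataset()], with exactly one
#'   true pair.
#' @return Logical scalar.
#' @export
correct_single_pair <- function(ranked, truth) {
  if (nrow(ranked) == 0) stop("empty ranking", call. = FALSE)
  tp <- truth$true_pairs
  if (nrow(tp) != 1) stop("single-pair rule needs exactly one true pair", call. = FALSE)
  setequal(c(ranked$i[1], ranked$j[1]), c(tp$i[1], tp$j[1]))
}

#' Accuracy rule: multiple independent interacting pairs
#'
#' A replicate counts as correct when every disease SNP appears in at least
#' one of the top-5 ranked pairs.
#'
#' @param ranked A `ranked_pairs` tibble with at least 5 entries.
#' @param truth A truth record listing the disease SNP set.
#' @return Logical scalar.
#' @export
correct_multi_pair <- function(ranked, truth) {
  if (nrow(ranked) < 5) stop("need at least 5 ranked pairs", call. = FALSE)
  top <- ranked[1:5, ]
  all(truth$disease_indices %in% c(top$i, top$j))
}

#' Accuracy rule: higher-order interaction network
#'
#' Takes the maximal prefix of the ranking in which every pair contains at
#' least one disease SNP (the run of consecutive disease-touching pairs from
#' rank 1), and counts the replicate correct when that prefix jointly covers
#' every disease SNP. The prefix ends at the first pair with no disease SNP;
#' pairs between one disease SNP and a background SNP may appear inside it.
#'
#' @param ranked A `ranked_pairs` tibble.
#' @param truth A truth record listing the network's disease SNP set.
#' @return Logical scalar.
#' @export
correct_higher_order <- function(ranked, truth) {
  if (nrow(ranked) == 0) stop("empty ranking", call. = FALSE)
  d <- truth$disease_indices
  touches <- ranked$i %in% d | ranked$j %in% d
  if (!touches[1]) return(FALSE)
  prefix_end <- if (all(touches)) nrow(ranked) else which(!touches)[1] - 1
  seen <- c(ranked$i[1:prefix_end], ranked$j[1:prefix_end])
  all(d %in% seen)
}

#' Accuracy over simulation replicates
#'
#' Applies the scenario's correctness rule to each (ranking, truth) replicate
#' and reports the percentage correct. Scenarios: `single_pair` (and
#' `single_pair_marginal`) use [correct_single_pair()], `multi_pair`
#' [correct_multi_pair()], `higher_order` [correct_higher_order()].
#'
#' @param ranked_list List of `ranked_pairs` tibbles.
#' @param truth_list Parallel list of truth records, all of one scenario.
#' @param scenario Scenario name; default taken from the truth records.
#' @return A one-row tibble: `scenario`, `n_datasets`, `n_correct`,
#'   `accuracy_pct`.
#' @export
accuracy_over_replicates <- function(ranked_list, truth_list, scenario = NULL) {
  stopifnot(length(ranked_list) == length(truth_list),
            length(ranked_list) >= 1)
  scen <- unique(vapply(truth_list, function(t) t$scenario %||% NA_character_,
                        character(1)))
  scen <- scen[!is.na(scen)]
  if (is.null(scenario)) {
    if (length(scen) != 1) stop("mixed or missing scenarios; pass `scenario`",
                                call. = FALSE)
    scenario <- scen
  } else if (length(scen) > 1) {
    stop("replicates mix scenarios: ", paste(scen, collapse = ", "),
         call. = FALSE)
  }
  rule <- switch(scenario,
    single_pair = correct_single_pair,
    single_pair_marginal = correct_single_pair,
    multi_pair = correct_multi_pair,
    higher_order = correct_higher_order,
    stop("unknown scenario '", scenario, "'", call. = FALSE)
  )
  ok <- vapply(seq_along(ranked_list),
               function(r) rule(ranked_list[[r]], truth_list[[r]]), logical(1))
  tibble::tibble(
    scenario = scenario,
    n_datasets = length(ok),
    n_correct = sum(ok),
    accuracy_pct = 100 * sum(ok) / length(ok)
  )
}

#' Empirical ROC over contrast-score thresholds
#'
#' At each threshold `t`: sensitivity is the fraction of true interacting
#' pairs with `rho_diff >= t`; specificity is the fraction of all other pairs
#' with `rho_diff < t`. Pairs between a disease SNP and a background SNP count
#' as negatives. The default grid is the sorted set of observed scores plus
#' `Inf` (exact empirical curve including both corners). The largest threshold
#' still achieving sensitivity 1 - equivalently the smallest true-pair score,
#' the "minimum score giving 100% sensitivity" - is attached as attribute
#' `min_full_sensitivity_threshold`.
#'
#' @param scores A `pair_scores` tibble (invalid pairs dropped).
#' @param truth A truth record with a nonempty `true_pairs` table.
#' @param thresholds Optional numeric grid.
#' @return A tibble of class `roc_curve`: `threshold`, `sensitivity`,
#'   `specificity`.
#' @export
roc_curve <- function(scores, truth, thresholds = NULL) {
  df <- dplyr::filter(tibble::as_tibble(scores), .data$valid)
  tp <- truth$true_pairs
  if (is.null(tp) || nrow(tp) == 0) stop("truth has no true pairs", call. = FALSE)
  key <- paste(pmin(df$i, df$j), pmax(df$i, df$j))
  truth_key <- paste(pmin(tp$i, tp$j), pmax(tp$i, tp$j))
  is_pos <- key %in% truth_key
  if (!any(is_pos)) stop("no true pair present among the scored pairs", call. = FALSE)
  if (is.null(thresholds)) thresholds <- c(sort(unique(df$rho_diff)), Inf)
  pos <- df$rho_diff[is_pos]
  neg <- df$rho_diff[!is_pos]
  out <- tibble::tibble(
    threshold = thresholds,
    sensitivity = vapply(thresholds, function(t) mean(pos >= t), numeric(1)),
    specificity = if (length(neg) == 0) rep(NA_real_, length(thresholds)) else
      vapply(thresholds, function(t) mean(neg < t), numeric(1))
  )
  full <- out$threshold[out$sensitivity == 1]
  attr(out, "min_full_sensitivity_threshold") <-
    if (length(full) > 0) max(full[is.finite(full)]) else NA_real_
  class(out) <- c("roc_curve", class(out))
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.roc_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$specificity,
                                   y = .data$sensitivity)) +
    ggplot2::geom_step(colour = "steelblue") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity") +
    ggplot2::theme_minimal()
}
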