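#' Run one stage of the simulate / scan / rank / evaluate pipeline
#'
#' Programmatic entry point behind the command-line wrapper shipped at
#' `inst/cli/epicontrast.R`. Each invocation runs one stage and writes its
#' outputs plus a JSON manifest (`<prefix>.manifest.json`) recording the
#' command, parameters, seed, and package version, so any output can be
#' regenerated exactly.
#'
#' Stages and their parameters (`params` list):
#' \describe{
#'   \item{simulate}{`model` (spec path), `n_case`, `n_control`, `n_snps`,
#'     `seed`, `out_prefix`. Writes `<prefix>.geno.tsv`, `<prefix>.pheno.tsv`,
#'     `<prefix>.truth.json`.}
#'   \item{scan}{`genotypes`, `labels` (TSV paths), `chunk_size`, `workers`,
#'     `out`. Writes the pair-score TSV.}
#'   \item{rank}{`pairs` (TSV path), `top_k`, `exact_sf`, `out`, optional
#'     `hubs` path.}
#'   \item{evaluate}{`ranked` (TSV path), `truth` (JSON path), `scenario`.
#'     Writes `<out>` with the decision; returns it too.}
#' }
#'
#' @param command One of `"simulate"`, `"scan"`, `"rank"`, `"evaluate"`.
#' @param params Named list of stage parameters (above).
#' @return Invisibly, a list with the stage's in-memory results. Unknown
#'   commands or missing required parameters raise a condition of class
#'   `usage_error`; runtime failures propagate as ordinary errors.
#' @export
run_pipeline <- function(command, params = list()) {
  commands <- c("simulate", "scan", "rank", "evaluate")
  if (length(command) != 1 || !command %in% commands) {
    usage_stop("unknown command '", paste(command, collapse = " "),
               "'; expected one of ", paste(commands, collapse = ", "))
  }
  need <- function(keys) {
    miss <- setdiff(keys, names(params))
    if (length(miss) > 0) {
      usage_stop("missing parameter(s) for '", command, "': ",
                 paste(miss, collapse = ", "))
    }
  }
  result <- switch(command,
    simulate = {
      need(c("model", "n_case", "n_control", "n_snps", "seed", "out_prefix"))
      model <- read_model_spec(params$model)
      sim <- simulate_dataset(model, params$n_case, params$n_control,
                              params$n_snps, seed = params$seed)
      write_genotype_tsv(sim$genotypes, paste0(params$out_prefix, ".geno.tsv"))
      write_phenotype_tsv(sim$phenotypes, paste0(params$out_prefix, ".pheno.tsv"))
      write_truth(sim$truth, paste0(params$out_prefix, ".truth.json"))
      write_manifest(command, params, paste0(params$out_prefix, ".manifest.json"))
      sim
    },
    scan = {
      need(c("genotypes", "labels", "out"))
      dat <- read_genotype_tsv(params$genotypes, params$labels)
      scores <- scan_pairs(dat$genotypes, dat$phenotypes,
                           chunk_size = params$chunk_size %||% 10000,
                           workers = params$workers %||% 1)
      write_pair_scores(scores, params$out)
      write_manifest(command, params, paste0(params$out, ".manifest.json"))
      n_invalid <- sum(!scores$valid)
      if (n_invalid > 0) {
        message(n_invalid, " pair(s) invalid (undefined rho in a group)")
      }
      list(scores = scores)
    },
    rank = {
      need(c("pairs", "out"))
      scores <- read_pair_scores(params$pairs)
      ranked <- rank_pairs(scores, k = params$top_k %||% 1000,
                           exact = isTRUE(params$exact_sf))
      write_ranked_pairs(ranked, params$out)
      if (!is.null(params$hubs)) {
        readr::write_tsv(detect_hubs(ranked), params$hubs, progress = FALSE)
      }
      write_manifest(command, params, paste0(params$out, ".manifest.json"))
      list(ranked = ranked)
    },
    evaluate = {
      need(c("ranked", "truth", "scenario"))
      ranked <- read_ranked_pairs(params$ranked)
      truth <- read_truth(params$truth)
      res <- accuracy_over_replicates(list(ranked), list(truth),
                                      scenario = params$scenario)
      if (!is.null(params$out)) {
        readr::write_tsv(res, params$out, progress = FALSE)
        write_manifest(command, params, paste0(params$out, ".manifest.json"))
      }
      list(result = res)
    }
  )
  invisible(result)
}

usage_stop <- function(...) {
  stop(structure(class = c("usage_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

write_manifest <- function(command, params, path) {
  jsonlite::write_json(
    list(command = command,
         params = params[order(names(params))],
         package = "epicontrast",
         version = as.character(utils::packageVersion("epicontrast")),
         timestamp = format(Sys.time(), tz = "UTC")),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}
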