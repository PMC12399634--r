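# Orchestration layer: each run_* function reads plain-file inputs, executes
# one analysis dimension, and writes CSV/JSON reports into an output
# directory. A JSON run-configuration file can drive all three (see
# read_run_config); the thin command-line wrapper in inst/cli calls straight
# into these functions.

#' Read a JSON run configuration
#'
#' Recognized fields: `metadata`, `texts`, `codings`, `scoresheets`,
#' `out_dir`, `stage_preset` (`"three-stage"` or `"evolution"`), `k`,
#' `k_candidates`, `iterations`, `beta`, `seed`, `top_n`, `min_count`,
#' `stopwords`.
#'
#' @param path JSON file path.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  jsonlite::read_json(path, simplifyVector = TRUE)
}

resolve_corpus <- function(config) {
  stopifnot(!is.null(config$metadata), !is.null(config$texts))
  load_corpus(config$metadata, config$texts,
              stage_preset(config$stage_preset %||% "three-stage"))
}

write_matrix_csv <- function(m, path, rowname_col) {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- rowname_col
  write.csv(df, path, row.names = FALSE)
}

#' Run the topic-model dimension end to end
#'
#' Tokenizes the corpus, builds counts, optionally selects the topic count
#' over `k_candidates`, fits the model, and writes `diagnostics.csv`
#' (when selection ran), `theta.csv`, `phi.csv`, `top_words.json`, and
#' `theme_intensity.csv` under `config$out_dir`.
#'
#' @param config list, as from [read_run_config()].
#' @return Invisibly, a list with the fitted model, the chosen k, and the
#'   output file paths.
#' @export
run_topic_pipeline <- function(config) {
  corpus <- resolve_corpus(config)
  out <- config$out_dir %||% "."
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  toks <- tokenize_corpus(corpus,
                          stopwords = config$stopwords %||% character())
  counts <- build_counts(toks, min_count = config$min_count %||% 1)
  seed <- config$seed %||% 42
  iters <- config$iterations %||% 100
  beta <- config$beta %||% 0.1
  diagnostics <- NULL
  if (!is.null(config$k)) {
    k <- config$k
  } else {
    cand <- config$k_candidates %||% 2:8
    sel <- select_k(counts, cand,
                    lda_config(2, beta = beta, iterations = iters,
                               seed = seed),
                    top_n = config$top_n %||% 10)
    k <- sel$k
    diagnostics <- sel$diagnostics
    write.csv(diagnostics, file.path(out, "diagnostics.csv"),
              row.names = FALSE)
  }
  model <- fit_lda(counts, lda_config(k, beta = beta, iterations = iters,
                                      seed = seed))
  write_matrix_csv(model$theta, file.path(out, "theta.csv"), "doc_id")
  write_matrix_csv(model$phi, file.path(out, "phi.csv"), "topic")
  tw <- lapply(seq_len(k), function(t)
    top_words(model, t, min(config$top_n %||% 10, length(model$vocabulary))))
  names(tw) <- rownames(model$phi)
  jsonlite::write_json(tw, file.path(out, "top_words.json"))
  ti <- theme_intensity(model, corpus)
  write_matrix_csv(ti, file.path(out, "theme_intensity.csv"), "stage")
  invisible(list(model = model, k = k, diagnostics = diagnostics,
                 files = file.path(out, c("theta.csv", "phi.csv",
                                          "top_words.json",
                                          "theme_intensity.csv"))))
}

#' Run the policy-tool dimension end to end
#'
#' Reads a codings CSV (header doc_id,coder_id,unit_id,category,subtool),
#' writes frequency and coverage tables, and, when the file contains two
#' coders over shared unit ids, a Cohen's kappa summary.
#'
#' @param config list with `codings` (CSV path) and `out_dir`.
#' @return Invisibly, list with the report, kappa (or NULL), and file paths.
#' @export
run_tool_pipeline <- function(config) {
  stopifnot(!is.null(config$codings))
  codings <- read.csv(config$codings, stringsAsFactors = FALSE)
  out <- config$out_dir %||% "."
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  frame <- default_coding_frame()
  coders <- unique(codings$coder_id %||% "A")
  primary <- if ("coder_id" %in% names(codings))
    codings[codings$coder_id == coders[1], ] else codings
  report <- tool_frequencies(primary, frame)
  write.csv(report$by_subtool, file.path(out, "tool_counts.csv"),
            row.names = FALSE)
  write.csv(report$by_category, file.path(out, "tool_categories.csv"),
            row.names = FALSE)
  kappa <- NULL
  if (length(coders) == 2) {
    a <- codings[codings$coder_id == coders[1], ]
    b <- codings[codings$coder_id == coders[2], ]
    shared <- intersect(a$unit_id, b$unit_id)
    if (length(shared) > 0) {
      ka <- cohen_kappa(a$category[match(shared, a$unit_id)],
                        b$category[match(shared, b$unit_id)])
      kappa <- list(kappa = ka$kappa, p_o = ka$p_o, p_e = ka$p_e,
                    n_units = ka$n_units)
    }
  }
  jsonlite::write_json(
    list(total_references = report$total, kappa = kappa),
    file.path(out, "tool_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(report = report, kappa = kappa,
                 files = file.path(out, c("tool_counts.csv",
                                          "tool_categories.csv",
                                          "tool_summary.json"))))
}

#' Run the policy-consistency dimension end to end
#'
#' Accepts either a secondary score-sheet CSV (policy_id, stage, fifty 0/1
#' columns X1_1..X9_7) or a primary-score CSV (policy_id, stage, X1..X9),
#' evaluates the cohort, and writes `pmc_results.csv`, `stage_summary.csv`,
#' and `surfaces.json`.
#'
#' @param config list with `scoresheets` (CSV path) and `out_dir`.
#' @return Invisibly, list with the `pmc_result`, the summary, and paths.
#' @export
run_pmc_pipeline <- function(config) {
  stopifnot(!is.null(config$scoresheets))
  tab <- read.csv(config$scoresheets, stringsAsFactors = FALSE,
                  check.names = FALSE)
  if (nrow(tab) == 0) stop("score-sheet file has no rows")
  out <- config$out_dir %||% "."
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  schema <- pmc_schema()
  sec_cols <- unlist(schema$secondaries, use.names = FALSE)
  if (all(sec_cols %in% names(tab))) {
    primaries <- t(apply(tab[, sec_cols], 1, function(r)
      aggregate_primary(setNames(as.numeric(r), sec_cols), schema)))
  } else if (all(schema$primaries %in% names(tab))) {
    primaries <- as.matrix(tab[, schema$primaries])
  } else {
    stop("score-sheet file must contain X1_1..X9_7 or X1..X9 columns")
  }
  res <- evaluate_policies(primaries, tab$policy_id,
                           stages = tab$stage %||% NULL)
  write.csv(res, file.path(out, "pmc_results.csv"), row.names = FALSE)
  summary <- NULL
  if (!anyNA(res$stage)) {
    summary <- cohort_summary(res)
    sm <- data.frame(group = c(names(summary$stage_means), "overall"),
                     mean_pmc = c(summary$stage_means,
                                  summary$overall_mean))
    write.csv(sm, file.path(out, "stage_summary.csv"), row.names = FALSE)
  }
  surfaces <- lapply(seq_len(nrow(res)), function(i) {
    sm <- surface_matrix(as.numeric(res[i, schema$primaries]))
    list(matrix = sm$matrix, flatness = sm$flatness)
  })
  names(surfaces) <- res$policy_id
  jsonlite::write_json(surfaces, file.path(out, "surfaces.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(results = res, summary = summary,
                 files = file.path(out, c("pmc_results.csv",
                                          "stage_summary.csv",
                                          "surfaces.json"))))
}
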