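#' The PMC indicator schema
#'
#' The Policy Modeling Consistency (PMC) index scores a policy text on nine
#' primary variables, each the mean of its binary secondary indicators, with
#' equal weights throughout. The default schema has secondary counts
#' (6, 3, 5, 7, 5, 8, 5, 4, 7) — fifty indicators in all — covering policy
#' nature, timeliness, function, focus, evaluation, audience, incentive
#' measures, issuing authority, and policy domains.
#'
#' @param secondary_counts integer vector, one entry per primary variable.
#' @param primary_labels optional descriptive labels, same length.
#' @return An object of class `pmc_schema`: list with `primaries` (codes
#'   X1..Xn), `primary_labels`, `secondary_counts`, and `secondaries`
#'   (codes `X1_1`, ..., grouped per primary).
#' @export
pmc_schema <- function(secondary_counts = c(6, 3, 5, 7, 5, 8, 5, 4, 7),
                       primary_labels = NULL) {
  stopifnot(all(secondary_counts >= 1))
  n <- length(secondary_counts)
  primaries <- paste0("X", seq_len(n))
  if (is.null(primary_labels) && n == 9)
    primary_labels <- c("policy nature", "policy timeliness",
                        "policy function", "policy focus",
                        "policy evaluation", "policy audience",
                        "incentive measures", "issuing authority",
                        "policy domains")
  secondaries <- lapply(seq_len(n), function(t)
    paste0(primaries[t], "_", seq_len(secondary_counts[t])))
  names(secondaries) <- primaries
  structure(list(primaries = primaries,
                 primary_labels = primary_labels %||% primaries,
                 secondary_counts = as.integer(secondary_counts),
                 secondaries = secondaries),
            class = "pmc_schema")
}

#' @export
print.pmc_schema <- function(x, ...) {
  cat(sprintf("PMC schema: %d primary variables, %d secondary indicators\n",
              length(x$primaries), sum(x$secondary_counts)))
  invisible(x)
}

#' Build a binary secondary score sheet from indicator evidence
#'
#' Each secondary indicator scores 1 when the policy text contains the
#' indicator's content and 0 otherwise.
#'
#' @param evidence named logical (or 0/1) vector covering every schema
#'   secondary exactly once (names `X1_1`, ...).
#' @param schema a [pmc_schema()].
#' @param policy_id identifier attached to the sheet.
#' @return An object of class `score_sheet`: named integer 0/1 vector with a
#'   `policy_id` attribute.
#' @export
score_secondary <- function(evidence, schema = pmc_schema(),
                            policy_id = "policy") {
  want <- unlist(schema$secondaries, use.names = FALSE)
  miss <- setdiff(want, names(evidence))
  if (length(miss)) stop_ids("missing secondary indicators", miss)
  extra <- setdiff(names(evidence), want)
  if (length(extra)) stop_ids("unknown secondary indicators", extra)
  vals <- as.integer(as.logical(evidence[want]))
  if (anyNA(vals)) stop("secondary evidence must be TRUE/FALSE or 0/1")
  structure(setNames(vals, want), policy_id = policy_id,
            class = "score_sheet")
}

#' Aggregate secondary indicators into primary-variable scores
#'
#' Primary score `x_t` is the mean of primary t's binary secondaries,
#' `sum_j X_tj / T_t`, rounded to two decimals with halves away from zero
#' (5/8 prints as 0.63).
#'
#' @param sheet a [score_secondary()] sheet (or compatible named 0/1 vector).
#' @param schema a [pmc_schema()].
#' @return Named numeric vector of primary scores (X1..Xn) with the sheet's
#'   `policy_id` attribute.
#' @export
aggregate_primary <- function(sheet, schema = pmc_schema()) {
  vals <- vapply(schema$primaries, function(p) {
    sec <- schema$secondaries[[p]]
    if (!all(sec %in% names(sheet))) stop_ids(
      "sheet is missing secondaries", setdiff(sec, names(sheet)))
    round_half_up(mean(as.numeric(sheet[sec])), 2)
  }, numeric(1))
  structure(vals, policy_id = attr(sheet, "policy_id"))
}

#' PMC index of a policy
#'
#' The sum of the nine (generally `n`) two-decimal primary scores, reported
#' at two decimals. Summing the rounded primaries, rather than the exact
#' fractions, is what the printed score tables of PMC studies tabulate.
#'
#' @param primary numeric vector of primary scores in `[0, 1]`.
#' @return Scalar PMC index in `[0, n]`.
#' @export
#' @examples
#' compute_pmc(c(0.83, 0.67, 1, 0.86, 1, 1, 1, 0.25, 1)) # 7.61
compute_pmc <- function(primary) {
  stopifnot(all(primary >= 0), all(primary <= 1))
  round_half_up(sum(primary), 2)
}

#' Grade a PMC index
#'
#' Consistency grade bins partition the scale: `[0, 4)` Poor, `[4, 6)`
#' Average, `[6, 8)` Good, `[8, 9]` Perfect.
#'
#' @param pmc_index numeric vector in `[0, 9]`.
#' @return Character vector of grades.
#' @export
pmc_grade <- function(pmc_index) {
  if (any(pmc_index < 0 | pmc_index > 9))
    stop("PMC index must lie in [0, 9]")
  as.character(cut(pmc_index, breaks = c(0, 4, 6, 8, 9),
                   labels = c("Poor", "Average", "Good", "Perfect"),
                   right = FALSE, include.lowest = TRUE))
}

#' Rank policies by PMC index
#'
#' Rank 1 is the highest index; exact ties keep input order (the earlier
#' policy takes the smaller rank).
#'
#' @param pmc_index numeric vector of indices in input (policy) order.
#' @return Integer vector of ranks.
#' @export
rank_policies <- function(pmc_index) {
  stopifnot(length(pmc_index) >= 1)
  ord <- order(-pmc_index)                 # stable: ties keep input order
  ranks <- integer(length(pmc_index))
  ranks[ord] <- seq_along(pmc_index)
  ranks
}

#' PMC surface matrix and flatness
#'
#' Arranges the nine primary scores row-major in a 3x3 grid — rows
#' (X1, X2, X3), (X4, X5, X6), (X7, X8, X9) — whose surface rendering shows a
#' policy's balance across dimensions. Flatness is the range (max minus min)
#' of the nine entries; smaller means a more internally consistent policy.
#'
#' @param primary numeric vector of nine primary scores.
#' @return List with `matrix` (3x3) and `flatness`.
#' @export
surface_matrix <- function(primary) {
  stopifnot(length(primary) == 9)
  m <- matrix(as.numeric(primary), nrow = 3, byrow = TRUE)
  list(matrix = m, flatness = max(primary) - min(primary))
}

#' Evaluate a cohort of policies: indices, grades, ranks, stage summaries
#'
#' @param primary_scores numeric matrix or data.frame, one row per policy and
#'   one column per primary variable (X1..Xn), values in `[0, 1]`.
#' @param policy_ids character vector of row identifiers.
#' @param stages optional character vector of stage labels per policy.
#' @return An object of class `pmc_result`: data.frame with policy_id, stage,
#'   X1..Xn, pmc_index, rank, grade.
#' @export
evaluate_policies <- function(primary_scores, policy_ids = NULL,
                              stages = NULL) {
  m <- as.matrix(primary_scores)
  storage.mode(m) <- "double"
  policy_ids <- policy_ids %||% rownames(m) %||%
    paste0("P", seq_len(nrow(m)))
  idx <- apply(m, 1, compute_pmc)
  res <- data.frame(policy_id = policy_ids,
                    stage = stages %||% NA_character_,
                    m, pmc_index = idx, rank = rank_policies(idx),
                    grade = pmc_grade(idx),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("pmc_result", "data.frame")
  res
}

#' Cohort summary: stage means, overall mean, per-primary means
#'
#' All means are arithmetic, reported at two decimals with halves away from
#' zero.
#'
#' @param results a [evaluate_policies()] result (stages must be filled in).
#' @return List with `stage_means` (named, in stage order of appearance),
#'   `overall_mean`, and `primary_means` (named X1..Xn).
#' @export
cohort_summary <- function(results) {
  stopifnot(inherits(results, "pmc_result"))
  if (anyNA(results$stage)) stop("every policy must carry a stage label")
  stages <- unique(results$stage)
  stage_means <- vapply(setNames(stages, stages), function(s) {
    rows <- results$pmc_index[results$stage == s]
    if (length(rows) == 0) stop(sprintf("stage '%s' has no policies", s))
    round_half_up(mean(rows), 2)
  }, numeric(1))
  pcols <- grep("^X[0-9]+$", names(results), value = TRUE)
  primary_means <- vapply(setNames(pcols, pcols), function(p)
    round_half_up(mean(results[[p]]), 2), numeric(1))
  list(stage_means = stage_means,
       overall_mean = round_half_up(mean(results$pmc_index), 2),
       primary_means = primary_means)
}

#' Worked 12-policy primary-score table
#'
#' A packaged fixture: the primary-variable scores (two decimals), stage
#' labels, and issue years of twelve representative national-fitness
#' policies, four from each of the three policy stages. Useful as a worked
#' example for the PMC engine and as a regression anchor.
#'
#' @return data.frame with policy_id, stage, year, X1..X9.
#' @export
#' @examples
#' tab <- example_primary_scores()
#' evaluate_policies(tab[, paste0("X", 1:9)], tab$policy_id, tab$stage)
example_primary_scores <- function() {
  path <- system.file("extdata", "nfp12_primary_scores.csv",
                      package = "policytriad")
  read.csv(path, stringsAsFactors = FALSE)
}
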