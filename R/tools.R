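#' Policy-tool coding frame
#'
#' The default frame is the Rothwell-Zegveld tripartite classification
#' adapted to mass-fitness policy: three categories (supply, environmental,
#' demand) with five named sub-tools each, fifteen in all.
#'
#' @return An object of class `coding_frame`: data.frame with columns
#'   `category` and `subtool`, in frame order.
#' @export
default_coding_frame <- function() {
  frame <- data.frame(
    category = rep(c("supply", "environmental", "demand"), each = 5),
    subtool = c(
      "Infrastructure", "Talent Development", "Technological Support",
      "Financial Investment", "Physical-medical integration",
      "Strategic Measures", "Goal Planning", "Regulatory Oversight",
      "Tax Incentives", "Financial Support",
      "Collaborative Development", "Outsourcing Services", "Pilot Projects",
      "International Exchange", "Government Procurement"),
    stringsAsFactors = FALSE)
  structure(frame, class = c("coding_frame", "data.frame"))
}

#' @rdname default_coding_frame
#' @param categories named list mapping category name to a character vector
#'   of sub-tool names; sub-tool names must be globally unique.
#' @export
coding_frame <- function(categories) {
  stopifnot(is.list(categories), length(categories) >= 1)
  frame <- data.frame(
    category = rep(names(categories), lengths(categories)),
    subtool = unlist(categories, use.names = FALSE),
    stringsAsFactors = FALSE)
  if (anyDuplicated(frame$subtool))
    stop_ids("duplicate sub-tool names",
             unique(frame$subtool[duplicated(frame$subtool)]))
  structure(frame, class = c("coding_frame", "data.frame"))
}

validate_codings <- function(codings, frame) {
  req <- c("doc_id", "subtool")
  miss <- setdiff(req, names(codings))
  if (length(miss)) stop_ids("codings are missing columns", miss)
  bad <- !codings$subtool %in% frame$subtool
  if (any(bad))
    stop_ids("sub-tools not in the coding frame",
             unique(codings$subtool[bad]))
  codings$category <- frame$category[match(codings$subtool, frame$subtool)]
  codings
}

#' Tabulate policy-tool usage frequencies and proportions
#'
#' Each coded segment counts as one reference; multiple references per
#' document per sub-tool all count. Proportions are percentages of the grand
#' total (overall) and of the category total (within-category), both to two
#' decimals, halves away from zero.
#'
#' @param codings data.frame of coded segments with at least `doc_id` and
#'   `subtool` (a `category` column, if present, is recomputed from the
#'   frame).
#' @param frame a [coding_frame()] (default [default_coding_frame()]).
#' @return An object of class `tool_frequency_report`: list with
#'   `by_subtool` (category, subtool, count, overall_pct, within_category_pct),
#'   `by_category` (category, count, overall_pct, coverage), and `total`.
#' @export
tool_frequencies <- function(codings, frame = default_coding_frame()) {
  codings <- validate_codings(codings, frame)
  total <- nrow(codings)
  if (total == 0) stop("no coded segments supplied")
  sub_counts <- vapply(frame$subtool,
                       function(s) sum(codings$subtool == s), integer(1))
  cat_levels <- unique(frame$category)
  cat_counts <- vapply(cat_levels,
                       function(ct) sum(sub_counts[frame$category == ct]),
                       integer(1))
  by_subtool <- data.frame(
    category = frame$category, subtool = frame$subtool,
    count = unname(sub_counts),
    overall_pct = round_half_up(100 * sub_counts / total, 2),
    within_category_pct = round_half_up(
      100 * sub_counts / cat_counts[frame$category], 2),
    row.names = NULL, stringsAsFactors = FALSE)
  by_category <- data.frame(
    category = cat_levels, count = unname(cat_counts),
    overall_pct = round_half_up(100 * cat_counts / total, 2),
    coverage = unname(category_coverage(codings, frame)[cat_levels]),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(by_subtool = by_subtool, by_category = by_category,
                 total = total),
            class = "tool_frequency_report")
}

#' @export
print.tool_frequency_report <- function(x, ...) {
  cat(sprintf("policy-tool usage: %d references\n", x$total))
  print(x$by_category, row.names = FALSE)
  invisible(x)
}

#' Distinct-document coverage per tool category
#'
#' @inheritParams tool_frequencies
#' @return Named integer vector: number of distinct documents with at least
#'   one reference in each category.
#' @export
category_coverage <- function(codings, frame = default_coding_frame()) {
  codings <- validate_codings(codings, frame)
  cat_levels <- unique(frame$category)
  vapply(setNames(cat_levels, cat_levels), function(ct)
    length(unique(codings$doc_id[codings$category == ct])), integer(1))
}

#' Cohen's kappa for two coders
#'
#' Chance-corrected agreement on a shared ordered set of coding units:
#' `kappa = (p_o - p_e) / (1 - p_e)` with `p_o` the fraction of units on
#' which the coders agree and `p_e = sum_c m_a(c) m_b(c)` the agreement
#' expected from the coders' marginal label frequencies. Identical label
#' vectors give kappa 1 even when `p_e = 1`.
#'
#' @param labels_a,labels_b equal-length label vectors (categories, possibly
#'   including `"none"`), unit i of one aligned with unit i of the other.
#' @return An object of class `reliability_result`: list with `kappa`, `p_o`,
#'   `p_e`, and `n_units`.
#' @export
#' @examples
#' cohen_kappa(c("a", "a", "b"), c("a", "a", "b"))$kappa # 1
cohen_kappa <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b))
  n <- length(labels_a)
  if (n == 0) stop("zero coding units")
  labels_a <- as.character(labels_a)
  labels_b <- as.character(labels_b)
  p_o <- mean(labels_a == labels_b)
  lev <- union(labels_a, labels_b)
  ma <- vapply(lev, function(l) mean(labels_a == l), numeric(1))
  mb <- vapply(lev, function(l) mean(labels_b == l), numeric(1))
  p_e <- sum(ma * mb)
  kappa <- if (p_e >= 1) {
    if (p_o == 1) 1 else NaN
  } else {
    (p_o - p_e) / (1 - p_e)
  }
  structure(list(kappa = kappa, p_o = p_o, p_e = p_e, n_units = n),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.4f (p_o = %.4f, p_e = %.4f, n = %d)\n",
              x$kappa, x$p_o, x$p_e, x$n_units))
  invisible(x)
}
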