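#' Stage configurations for a policy study window
#'
#' A stage configuration partitions the study window into named, ordered,
#' non-overlapping year intervals. Two presets ship with the package:
#' `"three-stage"` (the default: Initiation 1995-2000, Expansion 2001-2015,
#' Improvement 2016-2025, the periodization used for policy-consistency stage
#' summaries) and `"evolution"` (Initiation 1995-2000, Expansion 2001-2013,
#' Improvement 2014-2025, the variant used when narrating annual policy-count
#' trends).
#'
#' @param stages data.frame with columns `label`, `start_year`, `end_year`,
#'   ordered by time.
#' @return An object of class `stage_config`.
#' @export
#' @examples
#' stage_config(data.frame(label = c("early", "late"),
#'                         start_year = c(2000, 2011),
#'                         end_year = c(2010, 2020)))
stage_config <- function(stages) {
  stopifnot(is.data.frame(stages),
            all(c("label", "start_year", "end_year") %in% names(stages)))
  if (nrow(stages) == 0) stop("stage configuration must be non-empty")
  if (anyDuplicated(stages$label)) stop("stage labels must be unique")
  if (any(stages$start_year > stages$end_year))
    stop("stage start_year must not exceed end_year")
  o <- order(stages$start_year)
  stages <- stages[o, , drop = FALSE]
  if (nrow(stages) > 1 &&
      any(stages$start_year[-1] != stages$end_year[-nrow(stages)] + 1))
    stop("stage intervals must be contiguous and non-overlapping")
  rownames(stages) <- NULL
  structure(list(stages = stages), class = "stage_config")
}

#' @rdname stage_config
#' @param name preset name, `"three-stage"` or `"evolution"`.
#' @export
stage_preset <- function(name = c("three-stage", "evolution")) {
  name <- match.arg(name)
  tab <- switch(name,
    "three-stage" = data.frame(
      label = c("Initiation", "Expansion", "Improvement"),
      start_year = c(1995, 2001, 2016),
      end_year = c(2000, 2015, 2025)),
    "evolution" = data.frame(
      label = c("Initiation", "Expansion", "Improvement"),
      start_year = c(1995, 2001, 2014),
      end_year = c(2000, 2013, 2025)))
  stage_config(tab)
}

#' Load a dated policy corpus
#'
#' Combines a metadata table (id, title, date, issuer, level) with per-id
#' document texts into a validated corpus object. Texts may be supplied as a
#' named character vector, as a directory containing one UTF-8 `<id>.txt`
#' file per document, or as a JSON file mapping id to text.
#'
#' @param metadata data.frame with columns `id`, `title`, `date`, `issuer`,
#'   `level`, or the path of a CSV/TSV file with that header. Dates must be
#'   ISO-8601 (`YYYY-MM-DD`, `/` also accepted); `level` must be `"national"`
#'   or `"local"`.
#' @param texts named character vector (names are ids), a directory path, or
#'   a JSON file path.
#' @param stage_config a [stage_config()] (default: the three-stage preset).
#' @return An object of class `policy_corpus`: a list with a `documents`
#'   data.frame (id, title, date, issuer, level, text) and the stage
#'   configuration.
#' @export
load_corpus <- function(metadata, texts, stage_config = stage_preset()) {
  if (is.character(metadata) && length(metadata) == 1) {
    sep <- if (grepl("\\.tsv$", metadata)) "\t" else ","
    metadata <- read.csv(metadata, sep = sep, stringsAsFactors = FALSE,
                         colClasses = "character")
  }
  req <- c("id", "title", "date", "issuer", "level")
  miss <- setdiff(req, names(metadata))
  if (length(miss)) stop_ids("metadata is missing columns", miss)
  if (nrow(metadata) == 0) stop("corpus must contain at least one document")
  if (anyDuplicated(metadata$id))
    stop_ids("duplicate document ids",
             unique(metadata$id[duplicated(metadata$id)]))
  dates <- as.Date(gsub("/", "-", metadata$date))
  if (anyNA(dates))
    stop_ids("unparseable dates for ids", metadata$id[is.na(dates)])
  bad_level <- !metadata$level %in% c("national", "local")
  if (any(bad_level))
    stop_ids("level must be 'national' or 'local'; offending ids",
             metadata$id[bad_level])

  if (is.character(texts) && length(texts) == 1 && dir.exists(texts)) {
    files <- file.path(texts, paste0(metadata$id, ".txt"))
    ok <- file.exists(files)
    txt <- rep(NA_character_, length(files))
    txt[ok] <- vapply(files[ok], function(f)
      paste(readLines(f, warn = FALSE, encoding = "UTF-8"), collapse = "\n"),
      character(1))
    names(txt) <- metadata$id
    texts <- txt
  } else if (is.character(texts) && length(texts) == 1 &&
             grepl("\\.json$", texts)) {
    texts <- unlist(jsonlite::read_json(texts, simplifyVector = TRUE))
  }
  if (is.list(texts)) texts <- unlist(texts)
  stopifnot(is.character(texts), !is.null(names(texts)))
  txt <- texts[metadata$id]
  if (anyNA(txt))
    stop_ids("no text found for ids", metadata$id[is.na(txt)])

  documents <- data.frame(
    id = metadata$id, title = metadata$title, date = dates,
    issuer = metadata$issuer, level = metadata$level,
    text = unname(txt), stringsAsFactors = FALSE)
  structure(list(documents = documents, stage_config = stage_config),
            class = "policy_corpus")
}

#' @export
print.policy_corpus <- function(x, ...) {
  d <- x$documents
  cat(sprintf("policy corpus: %d documents, %s to %s\n", nrow(d),
              min(d$date), max(d$date)))
  cat("stages:", paste(sprintf("%s (%d-%d)", x$stage_config$stages$label,
                               x$stage_config$stages$start_year,
                               x$stage_config$stages$end_year),
                       collapse = ", "), "\n")
  invisible(x)
}

#' Tokenize document text
#'
#' Splits text into terms with a pluggable segmenter, then removes stopwords
#' and tokens shorter than `min_len`, preserving order. The default segmenter
#' splits on Unicode non-word characters; a Chinese-capable segmenter (e.g. a
#' jiebaR wrapper) can be passed instead, as long as it is a deterministic
#' function from text to a character vector.
#'
#' @param text a single character string.
#' @param segmenter function(text) -> character vector of tokens.
#' @param stopwords character vector of terms to drop.
#' @param min_len minimum token length in characters (default 1).
#' @return Character vector of tokens (possibly empty).
#' @export
#' @examples
#' tokenize("the national fitness plan", stopwords = "the")
tokenize <- function(text, segmenter = default_segmenter,
                     stopwords = character(), min_len = 1) {
  stopifnot(is.character(text), length(text) == 1)
  toks <- segmenter(text)
  toks <- toks[nzchar(toks)]
  toks <- toks[!(toks %in% stopwords)]
  toks[nchar(toks) >= min_len]
}

#' @rdname tokenize
#' @export
default_segmenter <- function(text) {
  unlist(strsplit(tolower(text), "[^\\p{L}\\p{N}_]+", perl = TRUE),
         use.names = FALSE)
}

#' @rdname tokenize
#' @param corpus a [load_corpus()] object.
#' @param ... passed on to [tokenize()].
#' @return `tokenize_corpus`: a named list of token vectors, one per document,
#'   in corpus order.
#' @export
tokenize_corpus <- function(corpus, ...) {
  stopifnot(inherits(corpus, "policy_corpus"))
  toks <- lapply(corpus$documents$text, tokenize, ...)
  names(toks) <- corpus$documents$id
  toks
}

#' Build a document-term count matrix
#'
#' Vocabulary is the lexicographically sorted set of terms whose total corpus
#' frequency is at least `min_count`. Documents emptied by the frequency
#' filter are retained as zero rows so the matrix stays aligned with the
#' corpus.
#'
#' @param tokens named list of token vectors (see [tokenize_corpus()]).
#' @param min_count minimum corpus frequency for a term to enter the
#'   vocabulary (default 1).
#' @return An object of class `dtm_counts`: list with `counts` (integer
#'   matrix, documents x terms, dimnames set), `vocabulary`, and `doc_lengths`
#'   (row sums).
#' @export
build_counts <- function(tokens, min_count = 1) {
  stopifnot(is.list(tokens), min_count >= 1)
  if (is.null(names(tokens))) names(tokens) <- paste0("d", seq_along(tokens))
  tot <- table(unlist(tokens, use.names = FALSE))
  vocab <- sort(names(tot[tot >= min_count]), method = "radix")
  if (length(vocab) == 0)
    stop("empty vocabulary after frequency filtering")
  counts <- matrix(0L, nrow = length(tokens), ncol = length(vocab),
                   dimnames = list(names(tokens), vocab))
  for (d in seq_along(tokens)) {
    tt <- table(factor(tokens[[d]], levels = vocab))
    counts[d, ] <- as.integer(tt)
  }
  structure(list(counts = counts, vocabulary = vocab,
                 doc_lengths = rowSums(counts)),
            class = "dtm_counts")
}

#' @export
print.dtm_counts <- function(x, ...) {
  cat(sprintf("document-term counts: %d documents x %d terms, %d tokens\n",
              nrow(x$counts), ncol(x$counts), sum(x$doc_lengths)))
  invisible(x)
}

#' Assign documents to policy stages by issue year
#'
#' @param dates a `Date` vector (or single date).
#' @param config a [stage_config()].
#' @return Character vector of stage labels.
#' @export
#' @examples
#' assign_stage(as.Date("1995-06-20"), stage_preset()) # "Initiation"
assign_stage <- function(dates, config = stage_preset()) {
  stopifnot(inherits(config, "stage_config"))
  yrs <- as.integer(format(as.Date(dates), "%Y"))
  st <- config$stages
  idx <- vapply(yrs, function(y) {
    hit <- which(y >= st$start_year & y <= st$end_year)
    if (length(hit) != 1)
      stop(sprintf("year %d is outside the configured stages", y),
           call. = FALSE)
    hit
  }, integer(1))
  st$label[idx]
}

#' Annual publication counts and per-level yearly means
#'
#' Tabulates documents per year per administrative level over a study window
#' and reports each level's mean annual count (total divided by the number of
#' years in the window, two decimals, halves away from zero).
#'
#' @param corpus a `policy_corpus`.
#' @param window integer vector of years, e.g. `1995:2024`.
#' @return List with `counts` (data.frame year x level, zero-filled) and
#'   `means` (named numeric per level).
#' @export
annual_counts <- function(corpus, window) {
  stopifnot(inherits(corpus, "policy_corpus"), length(window) >= 1)
  d <- corpus$documents
  yrs <- as.integer(format(d$date, "%Y"))
  levels_ <- c("national", "local")
  counts <- expand.grid(year = window, level = levels_,
                        stringsAsFactors = FALSE)
  counts$n <- mapply(function(y, l) sum(yrs == y & d$level == l),
                     counts$year, counts$level)
  means <- vapply(levels_, function(l)
    round_half_up(sum(counts$n[counts$level == l]) / length(window), 2),
    numeric(1))
  list(counts = counts, means = means)
}
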