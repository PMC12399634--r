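# Synthetic-data generators with known ground truth. All are deterministic
# under a fixed seed and emit objects that validate against the pipeline's
# loaders, so every stage can be tested without external data.

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(rgamma(n * k, shape = alpha), nrow = n, byrow = TRUE)
  x / rowSums(x)
}

#' Simulate a dated policy corpus from a topic-mixture generative model
#'
#' Draws topic-word distributions `phi_k ~ Dirichlet(topic_word_concentration)`
#' and per-document topic mixtures `theta_d ~ Dirichlet(doc_topic_concentration)`,
#' then generates tokens by ancestral sampling (topic, then word). Documents
#' receive synthetic ids, uniform-random issue dates within their configured
#' stage interval, and text equal to the space-joined tokens, so the corpus
#' round-trips through [tokenize_corpus()] and [assign_stage()].
#'
#' Defaults mirror a small national policy corpus: a few dozen documents of a
#' few hundred informative tokens each over a vocabulary of a few hundred
#' terms, with sparse (well-separated) topics.
#'
#' @param k_true number of generating topics.
#' @param vocab_size vocabulary size V; terms are `w000...`.
#' @param n_docs number of documents (ignored when `stage_docs` given).
#' @param doc_length tokens per document (single int or vector of length
#'   n_docs).
#' @param topic_word_concentration symmetric Dirichlet concentration for
#'   `phi` (default 0.05: sparse, well-separated topics).
#' @param doc_topic_concentration symmetric Dirichlet concentration for
#'   `theta` (default 0.1).
#' @param stage_docs optional named integer vector: documents per stage label
#'   of `stage_config` (names must match its labels, in order).
#' @param stage_config a [stage_config()] (default three-stage preset).
#' @param seed integer seed.
#' @return List with `corpus` (a `policy_corpus`), `counts` (a `dtm_counts`
#'   over the full synthetic vocabulary), and `truth` (list: `phi`, `theta`,
#'   `stages`).
#' @export
simulate_corpus <- function(k_true = 3, vocab_size = 200, n_docs = 52,
                            doc_length = 200,
                            topic_word_concentration = 0.05,
                            doc_topic_concentration = 0.1,
                            stage_docs = NULL,
                            stage_config = stage_preset(),
                            seed = 1) {
  stopifnot(k_true >= 1, vocab_size >= 2, n_docs >= 1,
            topic_word_concentration > 0, doc_topic_concentration > 0)
  set.seed(seed)
  st <- stage_config$stages
  if (is.null(stage_docs)) {
    base <- n_docs %/% nrow(st)
    stage_docs <- setNames(rep(base, nrow(st)), st$label)
    rem <- n_docs - base * nrow(st)
    if (rem > 0) stage_docs[seq_len(rem)] <- stage_docs[seq_len(rem)] + 1
  }
  stopifnot(identical(names(stage_docs), st$label))
  n_docs <- sum(stage_docs)
  if (length(doc_length) == 1) doc_length <- rep(doc_length, n_docs)
  stopifnot(length(doc_length) == n_docs, all(doc_length >= 1))

  vocab <- sprintf("w%03d", seq_len(vocab_size) - 1)
  phi <- rdirichlet(k_true, rep(topic_word_concentration, vocab_size))
  theta <- rdirichlet(n_docs, rep(doc_topic_concentration, k_true))
  colnames(phi) <- vocab

  stages <- rep(st$label, stage_docs)
  dates <- as.Date(unlist(lapply(seq_len(nrow(st)), function(s) {
    span <- seq(as.Date(sprintf("%d-01-01", st$start_year[s])),
                as.Date(sprintf("%d-12-31", st$end_year[s])), by = "day")
    sample(span, stage_docs[s], replace = TRUE)
  })), origin = "1970-01-01")

  ids <- sprintf("D%03d", seq_len(n_docs))
  counts <- matrix(0L, n_docs, vocab_size, dimnames = list(ids, vocab))
  texts <- character(n_docs)
  for (d in seq_len(n_docs)) {
    zs <- sample.int(k_true, doc_length[d], replace = TRUE, prob = theta[d, ])
    ws <- vapply(zs, function(z)
      sample.int(vocab_size, 1, prob = phi[z, ]), integer(1))
    tt <- tabulate(ws, nbins = vocab_size)
    counts[d, ] <- as.integer(tt)
    texts[d] <- paste(vocab[ws], collapse = " ")
  }

  metadata <- data.frame(
    id = ids, title = paste("synthetic policy", ids),
    date = as.character(dates), issuer = "synthetic",
    level = "national", stringsAsFactors = FALSE)
  corpus <- load_corpus(metadata, setNames(texts, ids), stage_config)
  dtm <- structure(list(counts = counts, vocabulary = vocab,
                        doc_lengths = rowSums(counts)),
                   class = "dtm_counts")
  list(corpus = corpus, counts = dtm,
       truth = list(phi = phi, theta = theta, stages = stages))
}

#' Simulate dual-coder policy-tool codings with controllable agreement
#'
#' Coder A labels each unit i.i.d. from `tool_distribution` (over the frame's
#' sub-tools plus `"none"`); coder B copies A's label with probability
#' `agreement` and otherwise redraws independently from the same
#' distribution. Under this scheme the expected category-level Cohen's kappa
#' equals `agreement` (see [expected_kappa()]).
#'
#' @param n_docs number of documents.
#' @param n_units_per_doc coding units per document.
#' @param tool_distribution named probability vector over
#'   `c(frame$subtool, "none")` (default uniform).
#' @param agreement probability in `[0, 1]` that coder B copies coder A.
#' @param frame a [coding_frame()].
#' @param seed integer seed.
#' @return List with `units` (data.frame doc_id, unit_id, label_a, label_b,
#'   category_a, category_b) and `codings` (data.frame of coder-A segments
#'   excluding "none": doc_id, coder_id, unit_id, category, subtool).
#' @export
simulate_codings <- function(n_docs = 52, n_units_per_doc = 20,
                             tool_distribution = NULL, agreement = 0.9,
                             frame = default_coding_frame(), seed = 1) {
  stopifnot(agreement >= 0, agreement <= 1, n_docs >= 1,
            n_units_per_doc >= 1)
  labels <- c(frame$subtool, "none")
  if (is.null(tool_distribution))
    tool_distribution <- setNames(rep(1 / length(labels), length(labels)),
                                  labels)
  stopifnot(identical(sort(names(tool_distribution)), sort(labels)),
            abs(sum(tool_distribution) - 1) < 1e-8)
  p <- tool_distribution[labels]
  set.seed(seed)
  n <- n_docs * n_units_per_doc
  a <- sample(labels, n, replace = TRUE, prob = p)
  copy <- runif(n) < agreement
  b <- ifelse(copy, a, sample(labels, n, replace = TRUE, prob = p))
  to_cat <- function(x) ifelse(x == "none", "none",
                               frame$category[match(x, frame$subtool)])
  units <- data.frame(
    doc_id = rep(sprintf("D%03d", seq_len(n_docs)), each = n_units_per_doc),
    unit_id = sprintf("u%05d", seq_len(n)),
    label_a = a, label_b = b,
    category_a = to_cat(a), category_b = to_cat(b),
    stringsAsFactors = FALSE)
  keep <- units$label_a != "none"
  codings <- data.frame(
    doc_id = units$doc_id[keep], coder_id = "A",
    unit_id = units$unit_id[keep],
    category = units$category_a[keep], subtool = units$label_a[keep],
    stringsAsFactors = FALSE)
  list(units = units, codings = codings)
}

#' Expected Cohen's kappa under the copy-or-redraw coder model
#'
#' If coder B copies coder A with probability `a` and otherwise redraws from
#' the same label distribution with collision probability `S = sum p_c^2`,
#' then `p_o = a + (1 - a) S`, `p_e = S`, and
#' `kappa = (p_o - p_e) / (1 - p_e) = a`: the expected kappa is the copy
#' probability, at any label granularity that is a function of the label.
#'
#' @param agreement copy probability.
#' @param probs label distribution (only needed to confirm `S < 1`).
#' @return The expected kappa (equal to `agreement`).
#' @export
expected_kappa <- function(agreement, probs) {
  S <- sum(probs^2)
  p_o <- agreement + (1 - agreement) * S
  (p_o - S) / (1 - S)
}

#' Simulate binary PMC score sheets
#'
#' Each secondary indicator is an independent Bernoulli draw with its primary
#' variable's fill probability.
#'
#' @param n_policies number of policies.
#' @param fill_probability scalar or per-primary vector of probabilities.
#' @param schema a [pmc_schema()].
#' @param seed integer seed.
#' @return data.frame: policy_id plus one 0/1 column per schema secondary.
#' @export
simulate_scoresheets <- function(n_policies, fill_probability = 0.5,
                                 schema = pmc_schema(), seed = 1) {
  np <- length(schema$primaries)
  if (length(fill_probability) == 1)
    fill_probability <- rep(fill_probability, np)
  stopifnot(length(fill_probability) == np,
            all(fill_probability >= 0), all(fill_probability <= 1))
  set.seed(seed)
  cols <- unlist(schema$secondaries, use.names = FALSE)
  prim_of <- rep(seq_len(np), schema$secondary_counts)
  m <- matrix(0L, n_policies, length(cols),
              dimnames = list(NULL, cols))
  for (j in seq_along(cols))
    m[, j] <- as.integer(runif(n_policies) < fill_probability[prim_of[j]])
  data.frame(policy_id = sprintf("P%04d", seq_len(n_policies)), m,
             stringsAsFactors = FALSE, check.names = FALSE)
}
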