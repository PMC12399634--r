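#' LDA sampler configuration
#'
#' Hyperparameters follow the common symmetric-prior convention for policy
#' corpora: `alpha = 50 / k` on the document-topic prior, `beta = 0.1` on the
#' topic-word prior, 100 Gibbs sweeps, and a fixed seed (42) so fits are
#' reproducible.
#'
#' @param k number of topics (>= 1).
#' @param alpha document-topic Dirichlet concentration (> 0, default `50 / k`).
#' @param beta topic-word Dirichlet concentration (> 0, default 0.1).
#' @param iterations number of full Gibbs sweeps (>= 1, default 100).
#' @param seed integer RNG seed (default 42).
#' @return An object of class `lda_config`.
#' @export
lda_config <- function(k, alpha = 50 / k, beta = 0.1, iterations = 100,
                       seed = 42) {
  stopifnot(k >= 1, alpha > 0, beta > 0, iterations >= 1)
  structure(list(k = as.integer(k), alpha = alpha, beta = beta,
                 iterations = as.integer(iterations),
                 seed = as.integer(seed)),
            class = "lda_config")
}

# Flatten a dtm_counts matrix into 0-based (doc, word) token streams in
# document order then vocabulary-index order.
token_stream <- function(counts) {
  m <- counts$counts
  idx <- which(t(m) > 0)             # column-major over t(m): doc-major order
  w <- (idx - 1) %% ncol(m)          # 0-based word index
  d <- (idx - 1) %/% ncol(m)         # 0-based doc index
  reps <- t(m)[idx]
  list(doc = as.integer(rep(d, reps)), word = as.integer(rep(w, reps)))
}

#' Fit a latent Dirichlet allocation topic model by collapsed Gibbs sampling
#'
#' Runs collapsed Gibbs sampling (theta and phi integrated out) from a seeded
#' uniform-random topic initialization for `config$iterations` full sweeps.
#' Point estimates are taken from the final sweep's count tables:
#' `theta[d, k] = (n_dk + alpha) / (n_d + K alpha)` and
#' `phi[k, w] = (n_kw + beta) / (n_k + V beta)`. The same configuration and
#' counts always give bit-identical results.
#'
#' @param counts a [build_counts()] object.
#' @param config an [lda_config()].
#' @return An object of class `topic_model`: list with `theta` (documents x
#'   topics), `phi` (topics x terms), `config`, `vocabulary`, `doc_ids`, and
#'   the final sampler `state` (`z`, `n_dk`, `n_kw`, `n_k`, `n_d`).
#' @export
fit_lda <- function(counts, config) {
  stopifnot(inherits(counts, "dtm_counts"), inherits(config, "lda_config"))
  n_tokens <- sum(counts$doc_lengths)
  if (n_tokens == 0) stop("cannot fit a topic model on an empty corpus")
  if (config$k > n_tokens)
    warning(sprintf("k = %d exceeds the corpus token count (%d)",
                    config$k, n_tokens))
  stream <- token_stream(counts)
  D <- nrow(counts$counts); V <- ncol(counts$counts); K <- config$k
  set.seed(config$seed)
  st <- gibbs_lda_cpp(stream$doc, stream$word, D, V, K,
                      config$alpha, config$beta, config$iterations)
  theta <- (st$n_dk + config$alpha) /
    (as.numeric(st$n_d) + K * config$alpha)
  phi <- (st$n_kw + config$beta) /
    (as.numeric(st$n_k) + V * config$beta)
  dimnames(theta) <- list(rownames(counts$counts), paste0("topic", seq_len(K)))
  dimnames(phi) <- list(paste0("topic", seq_len(K)), counts$vocabulary)
  structure(list(theta = theta, phi = phi, config = config,
                 vocabulary = counts$vocabulary,
                 doc_ids = rownames(counts$counts), state = st),
            class = "topic_model")
}

#' @export
print.topic_model <- function(x, ...) {
  cat(sprintf("LDA topic model: %d topics, %d documents, %d terms\n",
              x$config$k, nrow(x$theta), ncol(x$phi)))
  invisible(x)
}

#' Perplexity of a topic model on a document-term matrix
#'
#' `exp(-sum_dw n_dw log sum_k theta_dk phi_kw / N)` where `N` is the total
#' token count. Computed on the supplied counts, which must share the model's
#' vocabulary (the usual choice here is the training corpus).
#'
#' @param model a `topic_model`.
#' @param counts a `dtm_counts` over the same vocabulary and documents.
#' @return A positive scalar; lower is better.
#' @export
perplexity <- function(model, counts) {
  stopifnot(inherits(model, "topic_model"), inherits(counts, "dtm_counts"))
  if (!identical(model$vocabulary, counts$vocabulary))
    stop("counts vocabulary does not match the model vocabulary")
  n <- sum(counts$doc_lengths)
  if (n == 0) stop("zero total tokens")
  mix <- model$theta %*% model$phi           # documents x terms
  exp(-sum(counts$counts * log(mix)) / n)
}

#' Top terms of a topic
#'
#' @param model a `topic_model`.
#' @param topic topic index in `1..k`.
#' @param n number of terms; values above the vocabulary size are truncated
#'   with a warning. Ties in probability are broken lexicographically.
#' @return Character vector of `n` terms by descending topic-word probability.
#' @export
top_words <- function(model, topic, n) {
  stopifnot(inherits(model, "topic_model"),
            topic >= 1, topic <= model$config$k)
  V <- length(model$vocabulary)
  if (n > V) {
    warning(sprintf("n = %d exceeds vocabulary size %d; truncating", n, V))
    n <- V
  }
  p <- model$phi[topic, ]
  ord <- order(-p, model$vocabulary, method = "radix")
  model$vocabulary[ord][seq_len(n)]
}

# Document-frequency tables used by the coherence measures: D(w) = number of
# documents containing w, D(w1, w2) = number containing both.
doc_cooccurrence <- function(counts, words) {
  present <- counts$counts[, words, drop = FALSE] > 0
  crossprod(present)                           # words x words, D on diagonal
}

#' Topic coherence from document co-occurrence
#'
#' For each topic the `top_n` highest-probability words are scored by how
#' often they co-occur in documents. `umass` averages
#' `log((D(w_i, w_j) + 1) / D(w_j))` over ordered pairs `i < j` of the ranked
#' top words; `npmi` averages normalized pointwise mutual information with a
#' 1e-12 smoothing floor, so word pairs that never co-occur approach -1.
#' Higher is better for both.
#'
#' @param model a `topic_model`.
#' @param counts the `dtm_counts` providing document co-occurrence.
#' @param top_n number of top words per topic (>= 2, default 10; capped at V).
#' @param measure `"umass"` (default) or `"npmi"`.
#' @return List with `per_topic` (numeric vector) and `mean`.
#' @export
topic_coherence <- function(model, counts, top_n = 10,
                            measure = c("umass", "npmi")) {
  measure <- match.arg(measure)
  stopifnot(inherits(model, "topic_model"), inherits(counts, "dtm_counts"),
            top_n >= 2)
  if (!identical(model$vocabulary, counts$vocabulary))
    stop("counts vocabulary does not match the model vocabulary")
  top_n <- min(top_n, length(model$vocabulary))
  n_docs <- nrow(counts$counts)
  eps <- 1e-12
  per_topic <- vapply(seq_len(model$config$k), function(t) {
    words <- top_words(model, t, top_n)
    co <- doc_cooccurrence(counts, words)
    scores <- c()
    for (i in seq_len(top_n - 1)) {
      for (j in seq(i + 1, top_n)) {
        if (measure == "umass") {
          dj <- co[j, j]
          scores <- c(scores, log((co[i, j] + 1) / max(dj, 1)))
        } else {
          pi_ <- co[i, i] / n_docs
          pj <- co[j, j] / n_docs
          pij <- co[i, j] / n_docs
          pij_s <- max(pij, eps)
          scores <- c(scores,
                      log(pij_s / max(pi_ * pj, eps)) / (-log(pij_s)))
        }
      }
    }
    mean(scores)
  }, numeric(1))
  list(per_topic = per_topic, mean = mean(per_topic))
}

#' Select the number of topics by perplexity and coherence
#'
#' Fits each candidate `k` (with `alpha` re-derived as `50 / k`), records
#' training perplexity and mean coherence, and picks the `k` maximizing the
#' rank sum of the two criteria (high coherence good, low perplexity good).
#' Ties go to the smaller `k`.
#'
#' @param counts a `dtm_counts`.
#' @param k_candidates integer vector of at least two candidate topic counts.
#' @param base_config an [lda_config()] supplying beta, iterations, and seed.
#' @param top_n,measure passed to [topic_coherence()].
#' @return List with `k` (chosen) and `diagnostics` (data.frame of k,
#'   perplexity, coherence).
#' @export
select_k <- function(counts, k_candidates, base_config = lda_config(2),
                     top_n = 10, measure = "umass") {
  stopifnot(length(k_candidates) >= 2)
  k_candidates <- as.integer(k_candidates)
  diag_ <- data.frame(k = k_candidates, perplexity = NA_real_,
                      coherence = NA_real_)
  for (i in seq_along(k_candidates)) {
    k <- k_candidates[i]
    cfg <- lda_config(k, alpha = 50 / k, beta = base_config$beta,
                      iterations = base_config$iterations,
                      seed = base_config$seed)
    m <- fit_lda(counts, cfg)
    diag_$perplexity[i] <- perplexity(m, counts)
    diag_$coherence[i] <- topic_coherence(m, counts, top_n, measure)$mean
  }
  score <- rank(diag_$coherence) + rank(-diag_$perplexity)
  best <- which(score == max(score))
  chosen <- min(k_candidates[best])        # ties -> smaller k
  list(k = chosen, diagnostics = diag_)
}

#' Stage-wise theme intensity
#'
#' The per-stage mean document-topic proportion: entry (s, t) is the mean of
#' `theta[d, t]` over documents issued in stage s, so each stage row sums to
#' one and traces a topic's prominence across policy periods. Stages with no
#' documents yield `NA` rows.
#'
#' @param model a `topic_model` fitted on the corpus' documents (1:1 aligned).
#' @param corpus the `policy_corpus` providing issue dates and stages.
#' @return Matrix stages x topics with dimnames.
#' @export
theme_intensity <- function(model, corpus) {
  stopifnot(inherits(model, "topic_model"), inherits(corpus, "policy_corpus"))
  if (!identical(model$doc_ids, corpus$documents$id))
    stop("model documents do not align with the corpus")
  stages <- assign_stage(corpus$documents$date, corpus$stage_config)
  labels <- corpus$stage_config$stages$label
  out <- matrix(NA_real_, nrow = length(labels), ncol = model$config$k,
                dimnames = list(labels, colnames(model$theta)))
  for (s in labels) {
    rows <- which(stages == s)
    if (length(rows) > 0)
      out[s, ] <- colMeans(model$theta[rows, , drop = FALSE])
  }
  out
}
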