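# Independent oracle: closed-form smoothed-unigram perplexity for a
# single-topic model, computed straight from the count matrix.
unigram_perplexity <- function(counts, beta) {
  cw <- colSums(counts$counts)
  n <- sum(cw)
  q <- (cw + beta) / (n + length(cw) * beta)
  exp(-sum(cw * log(q)) / n)
}

fake_model <- function(theta, phi, vocab, doc_ids) {
  structure(list(theta = theta, phi = phi,
                 config = lda_config(nrow(phi)),
                 vocabulary = vocab, doc_ids = doc_ids, state = NULL),
            class = "topic_model")
}

test_that("k = 1 collapses to the smoothed corpus unigram model", {
  bc <- build_counts(ab_tokens())
  m <- fit_lda(bc, lda_config(1, beta = 0.1, iterations = 5))
  expect_equal(unname(m$theta[, 1]), c(1, 1))
  cw <- colSums(bc$counts)
  expect_equal(unname(m$phi[1, ]),
               unname((cw + 0.1) / (sum(cw) + 3 * 0.1)))
  expect_equal(perplexity(m, bc), unigram_perplexity(bc, 0.1),
               tolerance = 1e-12)
})

test_that("identical configuration gives bit-identical fits", {
  sim <- simulate_corpus(k_true = 2, vocab_size = 25, n_docs = 12,
                         doc_length = 50, seed = 3)
  cfg <- lda_config(3, iterations = 30, seed = 42)
  m1 <- fit_lda(sim$counts, cfg)
  m2 <- fit_lda(sim$counts, cfg)
  expect_identical(m1$theta, m2$theta)
  expect_identical(m1$phi, m2$phi)
  expect_identical(m1$state$z, m2$state$z)
  m3 <- fit_lda(sim$counts, lda_config(3, iterations = 30, seed = 43))
  expect_false(identical(m1$theta, m3$theta))
})

test_that("sampler state conserves counts and distributions normalize", {
  sim <- simulate_corpus(k_true = 3, vocab_size = 30, n_docs = 15,
                         doc_length = 60, seed = 11)
  m <- fit_lda(sim$counts, lda_config(4, iterations = 20))
  st <- m$state
  expect_equal(unname(rowSums(st$n_dk)), unname(sim$counts$doc_lengths))
  expect_equal(unname(colSums(st$n_dk)), as.vector(st$n_k))
  expect_equal(unname(rowSums(st$n_kw)), as.vector(st$n_k))
  expect_true(all(st$n_dk >= 0) && all(st$n_kw >= 0))
  expect_equal(unname(rowSums(m$theta)), rep(1, nrow(m$theta)),
               tolerance = 1e-9)
  expect_equal(unname(rowSums(m$phi)), rep(1, nrow(m$phi)),
               tolerance = 1e-9)
  expect_true(all(m$theta > 0) && all(m$phi > 0))
})

test_that("perplexity of a uniform model equals the vocabulary size", {
  bc <- build_counts(ab_tokens())
  V <- 3
  m <- fake_model(theta = matrix(0.5, 2, 2),
                  phi = matrix(1 / V, 2, V),
                  vocab = bc$vocabulary, doc_ids = rownames(bc$counts))
  expect_equal(perplexity(m, bc), V, tolerance = 1e-12)
})

test_that("top_words ranks by probability with lexicographic ties", {
  bc <- build_counts(ab_tokens())
  m <- fake_model(theta = matrix(1, 1, 1),
                  phi = matrix(c(0.5, 0.3, 0.2), 1, 3),
                  vocab = c("a", "b", "c"), doc_ids = c("d1", "d2"))
  expect_equal(top_words(m, 1, 2), c("a", "b"))

  m2 <- fake_model(theta = matrix(1, 1, 1),
                   phi = matrix(c(0.2, 0.4, 0.4), 1, 3),
                   vocab = c("a", "b", "c"), doc_ids = "d1")
  expect_equal(top_words(m2, 1, 2), c("b", "c"))
  expect_equal(top_words(m2, 1, 3), c("b", "c", "a"))
  expect_warning(res <- top_words(m2, 1, 5), "truncat")
  expect_equal(length(res), 3)
})

test_that("umass coherence matches a hand count on a toy corpus", {
  # three docs; top words chosen so the fake model ranks w1 then w2
  toks <- list(d1 = c("w1", "w2"), d2 = c("w1", "w2"), d3 = c("w1", "w3"))
  bc <- build_counts(toks)
  m <- fake_model(theta = matrix(1, 3, 1),
                  phi = matrix(c(0.5, 0.3, 0.2), 1, 3),
                  vocab = bc$vocabulary, doc_ids = names(toks))
  # top 2 words: w1 (D=3), w2 (D=2); co-occurrence D(w1,w2)=2
  got <- topic_coherence(m, bc, top_n = 2, measure = "umass")
  expect_equal(got$per_topic, log((2 + 1) / 2))
  expect_equal(got$mean, log(1.5))
})

test_that("npmi coherence approaches -1 for words that never co-occur", {
  toks <- list(d1 = c("w1", "w1"), d2 = c("w2", "w2"))
  bc <- build_counts(toks)
  m <- fake_model(theta = matrix(1, 2, 1),
                  phi = matrix(c(0.6, 0.4), 1, 2),
                  vocab = bc$vocabulary, doc_ids = names(toks))
  got <- topic_coherence(m, bc, top_n = 2, measure = "npmi")
  expect_lt(got$mean, -0.9)
})

test_that("coherence is invariant to document order", {
  sim <- simulate_corpus(k_true = 2, vocab_size = 20, n_docs = 8,
                         doc_length = 30, seed = 5)
  m <- fit_lda(sim$counts, lda_config(2, iterations = 20))
  perm <- c(5, 3, 8, 1, 7, 2, 6, 4)
  counts_perm <- sim$counts
  counts_perm$counts <- counts_perm$counts[perm, ]
  counts_perm$doc_lengths <- counts_perm$doc_lengths[perm]
  for (meas in c("umass", "npmi")) {
    expect_equal(topic_coherence(m, sim$counts, 5, meas)$per_topic,
                 topic_coherence(m, counts_perm, 5, meas)$per_topic)
  }
})

test_that("theme_intensity averages theta within stages", {
  # two stages, two docs each, hand-set theta
  metadata <- data.frame(
    id = c("a", "b", "c", "d"), title = "t",
    date = c("1996-01-01", "1998-01-01", "2018-01-01", "2020-01-01"),
    issuer = "i", level = "national", stringsAsFactors = FALSE)
  corpus <- load_corpus(metadata, setNames(rep("x", 4), metadata$id))
  theta <- rbind(c(0.9, 0.1), c(0.7, 0.3), c(0.2, 0.8), c(0.4, 0.6))
  m <- fake_model(theta = theta, phi = matrix(0.5, 2, 2),
                  vocab = c("x", "y"), doc_ids = metadata$id)
  ti <- theme_intensity(m, corpus)
  expect_equal(unname(ti["Initiation", ]), c(0.8, 0.2))
  expect_equal(unname(ti["Improvement", ]), c(0.3, 0.7))
  # stage with no documents -> NA row, not zeros
  expect_true(all(is.na(ti["Expansion", ])))
  expect_equal(unname(rowSums(ti[c(1, 3), ])), c(1, 1), tolerance = 1e-9)
})

test_that("topic recovery improves with corpus size", {
  sizes <- c(20, 50, 200)
  mean_tv <- vapply(sizes, function(n) {
    tvs <- vapply(1:5, function(s) {
      sim <- simulate_corpus(k_true = 3, vocab_size = 40, n_docs = n,
                             doc_length = 60,
                             topic_word_concentration = 0.1, seed = s)
      m <- fit_lda(sim$counts, lda_config(3, iterations = 60, seed = s))
      mean(match_tv(m$phi, sim$truth$phi))
    }, numeric(1))
    mean(tvs)
  }, numeric(1))
  expect_true(all(diff(mean_tv) < 0))
})

test_that("select_k requires at least two candidates and favours dominance", {
  sim <- simulate_corpus(k_true = 3, vocab_size = 40, n_docs = 60,
                         doc_length = 80, seed = 9)
  expect_error(select_k(sim$counts, 4), "length")
  sel <- select_k(sim$counts, c(2, 3), lda_config(2, seed = 9))
  expect_true(sel$k %in% c(2, 3))
  expect_equal(nrow(sel$diagnostics), 2)
  expect_true(all(sel$diagnostics$perplexity > 0))
  # the chosen k must maximize the rank-sum of the two criteria
  score <- rank(sel$diagnostics$coherence) +
    rank(-sel$diagnostics$perplexity)
  expect_equal(sel$k, min(sel$diagnostics$k[score == max(score)]))
})
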