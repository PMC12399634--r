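# Shared fixtures, all built in code.

toy_metadata <- function() {
  data.frame(
    id = c("P1", "P2", "P3"),
    title = c("fitness outline", "implementation opinions", "reform plan"),
    date = c("1995-06-20", "2011-02-15", "2021-07-18"),
    issuer = c("council", "council", "ministry"),
    level = c("national", "national", "local"),
    stringsAsFactors = FALSE)
}

toy_texts <- function() {
  c(P1 = "national fitness plan fitness",
    P2 = "sports reform and fitness services",
    P3 = "public health and community sports")
}

toy_corpus <- function() load_corpus(toy_metadata(), toy_texts())

# Two-document corpus matching the build_counts worked examples.
ab_tokens <- function() list(d1 = c("a", "b", "a"), d2 = c("b", "c"))

# Greedy best-match total-variation distance between estimated and true
# topic-word rows (oracle used by the recovery tests).
match_tv <- function(phi_hat, phi_true) {
  k <- nrow(phi_true)
  used <- integer(0)
  tvs <- numeric(k)
  for (t in seq_len(k)) {
    d <- apply(phi_hat, 1, function(r) 0.5 * sum(abs(r - phi_true[t, ])))
    d[used] <- Inf
    j <- which.min(d)
    used <- c(used, j)
    tvs[t] <- d[j]
  }
  tvs
}

# Expand per-subtool reference counts into one coded segment per reference.
segments_from_counts <- function(counts_by_subtool, docs_per_subtool = "D1") {
  data.frame(
    doc_id = docs_per_subtool,
    subtool = rep(names(counts_by_subtool), counts_by_subtool),
    stringsAsFactors = FALSE)
}

table6_results <- function() {
  tab <- example_primary_scores()
  evaluate_policies(tab[, paste0("X", 1:9)], tab$policy_id, tab$stage)
}
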