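# Shared oracles and toy-population builders for the test suite.

# Scalar-loop oracle for attraction matrices: applies the exported scalar
# operation per (chooser, candidate) pair, with the euclidean family negated
# as the matrix builder documents.
scalar_attraction <- function(rule, pref_row, trait_row) {
  p <- length(trait_row)
  k <- rule_pref_width(rule)
  B <- matrix(pref_row, nrow = p, ncol = k, byrow = TRUE)
  switch(rule,
    euclidean = , random = , pref_update =
      -attraction_euclidean(drop(B), trait_row),
    cosine = attraction_cosine(drop(B), trait_row),
    aspiration = attraction_aspiration(B, trait_row),
    linear = attraction_linear(B[, 1], B[, 2], trait_row),
    curvilinear = attraction_curvilinear(B[, 1], B[, 2], trait_row),
    polynomial = attraction_polynomial(B, trait_row))
}

attraction_matrix_oracle <- function(rule, prefs, traits) {
  out <- matrix(NA_real_, nrow(prefs), nrow(traits))
  for (i in seq_len(nrow(prefs)))
    for (j in seq_len(nrow(traits)))
      out[i, j] <- scalar_attraction(rule, prefs[i, ], traits[j, ])
  out
}

# Naive repeated-argmax matcher (lowest row-then-column index on ties).
naive_greedy <- function(mutual) {
  female <- integer(0); male <- integer(0); score <- numeric(0)
  for (i in seq_len(min(dim(mutual)))) {
    mx <- max(mutual)
    if (!is.finite(mx)) break
    hits <- which(mutual == mx, arr.ind = TRUE)
    b <- hits[order(hits[, 1], hits[, 2])[1], , drop = TRUE]
    female <- c(female, b[[1]]); male <- c(male, b[[2]]); score <- c(score, mx)
    mutual[b[[1]], ] <- -Inf; mutual[, b[[2]]] <- -Inf
  }
  data.frame(female = female, male = male, score = score)
}

# Hand-built population for metric fixtures.
make_toy_pop <- function(traits, prefs, sex, rule = "euclidean",
                         optimum = NULL, mate_pairs = NULL) {
  n <- nrow(traits); p <- ncol(traits)
  pop <- structure(list(
    id = sprintf("toy_a%d", seq_len(n)), sex = sex,
    traits = traits, prefs = prefs,
    ideal = implied_ideal_all(prefs, rule),
    energy = numeric(n), mate_id = rep(NA_character_, n),
    rule = rule, k = rule_pref_width(rule), n_traits = p,
    optimum = if (is.null(optimum)) rep(4, p) else optimum,
    generation = 0L, seed = 1L, run_label = "toy"),
    class = "mm_population")
  pop$energy <- compute_energy(traits, pop$optimum)
  if (!is.null(mate_pairs)) for (pr in mate_pairs) {
    pop$mate_id[pr[1]] <- pop$id[pr[2]]
    pop$mate_id[pr[2]] <- pop$id[pr[1]]
  }
  pop
}

random_pref_matrix <- function(rule, n, p) {
  matrix(stats::runif(n * p * rule_pref_width(rule), -10, 10),
         nrow = n)
}
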