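#' Simulation configuration
#'
#' Bundles every knob of one model run. The canonical parameter grid crosses
#' mutation noise sd in \{0.06, 0.15, 0.30\} (1%, 2.5% and 5% of the 6-unit
#' trait range) with selection strength in \{0.10, 0.15, 0.20\} (a 10-20%
#' reproductive advantage of the highest- over the lowest-energy couple).
#'
#' @param rule integration rule, or a null-model name (`"random"`,
#'   `"pref_update"`; both score attraction as Euclidean distance).
#' @param pairing `"product"` (mutual-attraction product), `"minimum"`
#'   (least-attracted member limits the couple), `"random"`, or
#'   `"pref_update"` (random pairing followed by moving preferences
#'   `update_fraction` of the way toward the chosen mate). Defaults to the
#'   canonical pairing for the rule.
#' @param n_agents population size (even; default 200).
#' @param n_traits trait dimensions (default 20).
#' @param generations generations of simulated evolution (default 200).
#' @param mutation_sd sd of the normal noise added to offspring traits.
#' @param selection_strength reproductive advantage `s`; sampling weight of
#'   the best couple is exactly `1 + s` times the worst couple's.
#' @param runs replicate runs for [run_sweep()] (default 50).
#' @param search_k optional; if set, each agent evaluates only `search_k`
#'   random candidates (incomplete mate search).
#' @param update_fraction preference-update step for the `pref_update`
#'   pairing (default 0.9).
#' @param selection `"capped"` (default): couples are sampled with
#'   [roulette_weights()], so the best couple has exactly a `1 + s`
#'   advantage over the worst. `"proportional"`: couple weights are the sum
#'   of the partners' raw inverse deviations from the optimum
#'   (`1/sum(|trait - optimum|)` each), an uncapped
#'   fitness-proportional wheel under which selection never saturates as
#'   the population approaches the optimum; see the methods vignette for
#'   when this regime is the appropriate one.
#' @param mutate_prefs if `TRUE`, offspring preference values receive the
#'   same `N(0, mutation_sd)` noise as traits (default `FALSE`: mutation
#'   noise on traits only, preference variation arises from recombination).
#' @param seed integer root seed.
#' @return an `mm_config` list.
#' @export
sim_config <- function(rule = "euclidean", pairing = NULL, n_agents = 200L,
                       n_traits = 20L, generations = 200L,
                       mutation_sd = 0.15, selection_strength = 0.15,
                       runs = 50L, search_k = NULL, update_fraction = 0.9,
                       selection = c("capped", "proportional"),
                       mutate_prefs = FALSE, seed = 1L) {
  selection <- match.arg(selection)
  rule <- match.arg(rule, names(.RULES))
  if (is.null(pairing))
    pairing <- switch(rule, random = "random", pref_update = "pref_update",
                      "product")
  pairing <- match.arg(pairing, c("product", "minimum", "random",
                                  "pref_update"))
  if (mutation_sd <= 0) stop("mutation_sd must be positive")
  if (selection_strength < 0) stop("selection_strength must be non-negative")
  if (generations < 1) stop("generations must be at least 1")
  structure(list(rule = rule, pairing = pairing,
                 n_agents = as.integer(n_agents),
                 n_traits = as.integer(n_traits),
                 generations = as.integer(generations),
                 mutation_sd = mutation_sd,
                 selection_strength = selection_strength,
                 runs = as.integer(runs), search_k = search_k,
                 update_fraction = update_fraction,
                 selection = selection, mutate_prefs = mutate_prefs,
                 seed = as.integer(seed)),
            class = "mm_config")
}

#' The eight canonical market models
#'
#' Six preference-integration rules paired by mutual attraction, plus the two
#' null models (random pairing; random pairing with preference updating).
#'
#' @param ... arguments passed on to [sim_config()] for every model.
#' @return named list of `mm_config` objects.
#' @export
model_configs <- function(...) {
  models <- c("euclidean", "cosine", "aspiration", "linear", "curvilinear",
              "polynomial", "random", "pref_update")
  out <- lapply(models, function(m) sim_config(rule = m, ...))
  names(out) <- models
  out
}

#' Agent energy: inverse deviation from the optimal trait vector
#'
#' `energy = 1 - sum(|trait - optimum|) / (n * 6)`, clamped to \[0, 1\]: the
#' denominator is the largest possible summed deviation on the 1-7 trait
#' scale, so an agent sitting exactly on the optimum has energy 1 and a
#' maximally deviant agent has energy 0. Evolved traits may drift outside
#' \[1, 7\] (they are not clamped after mutation), hence the floor at 0.
#'
#' @param traits trait vector, or a matrix with one agent per row.
#' @param optimum the run's optimal trait vector.
#' @return energy value(s) in \[0, 1\].
#' @export
compute_energy <- function(traits, optimum) {
  traits <- rbind(traits)
  if (ncol(traits) != length(optimum))
    stop("traits and optimum differ in length")
  dev <- rowSums(abs(sweep(traits, 2, optimum)))
  unname(.clamp(1 - dev / (6 * length(optimum)), 0, 1))
}

#' Roulette-wheel sampling weights for couples
#'
#' Maps pooled couple energies affinely so the minimum maps to 1 and the
#' maximum to `1 + s`, then normalizes to probabilities: the highest-energy
#' couple is sampled exactly `(1 + s)` times as often as the lowest-energy
#' couple. Constant energies (or `s = 0`) give a uniform wheel.
#'
#' @param couple_energies pooled energies, one per couple.
#' @param s selection strength.
#' @return probability vector summing to 1.
#' @export
roulette_weights <- function(couple_energies, s) {
  n <- length(couple_energies)
  if (n == 0) stop("no couples to weight")
  lo <- min(couple_energies); hi <- max(couple_energies)
  w <- if (hi > lo) 1 + s * (couple_energies - lo) / (hi - lo) else rep(1, n)
  w / sum(w)
}

#' Produce the next generation from a matching
#'
#' Samples `n_agents` couples with replacement, with probabilities from
#' [roulette_weights()] on pooled (summed) couple energies. Each sampled
#' couple produces one offspring: every trait value is copied from mother or
#' father with probability 1/2 and perturbed by `N(0, mutation_sd)` noise;
#' the preference block is inherited per trait dimension (the whole row of
#' preference values for that dimension) from one parent with probability
#' 1/2, without noise. Offspring sexes are an exact half/half random
#' permutation and parents die (non-overlapping generations).
#'
#' Uses the caller's RNG stream; seed at the run level.
#'
#' @param matching an `mm_matching` (indices within each sex, in the order
#'   females/males appear in `pop`).
#' @param pop the parental `mm_population`.
#' @param cfg an `mm_config`.
#' @return the offspring `mm_population`.
#' @export
reproduce <- function(matching, pop, cfg) {
  if (nrow(matching) == 0) stop("cannot reproduce from an empty matching")
  idx_f <- which(pop$sex == "female"); idx_m <- which(pop$sex == "male")
  mothers_pool <- idx_f[matching$female]
  fathers_pool <- idx_m[matching$male]
  if (is.null(cfg$selection) || cfg$selection == "capped") {
    pooled <- pop$energy[mothers_pool] + pop$energy[fathers_pool]
    w <- roulette_weights(pooled, cfg$selection_strength)
  } else {
    dev <- function(ix) pmax(
      rowSums(abs(sweep(pop$traits[ix, , drop = FALSE], 2, pop$optimum))),
      1e-6)
    w <- 1 / dev(mothers_pool) + 1 / dev(fathers_pool)
    w <- w / sum(w)
  }

  n <- cfg$n_agents; p <- pop$n_traits; k <- pop$k
  draws <- sample.int(nrow(matching), n, replace = TRUE, prob = w)
  mo <- mothers_pool[draws]; fa <- fathers_pool[draws]

  pick_t <- matrix(stats::runif(n * p) < 0.5, n, p)
  traits <- ifelse(pick_t, pop$traits[mo, , drop = FALSE],
                   pop$traits[fa, , drop = FALSE]) +
    stats::rnorm(n * p, 0, cfg$mutation_sd)

  pick_p <- matrix(stats::runif(n * p) < 0.5, n, p)
  pick_wide <- pick_p[, rep(seq_len(p), each = k), drop = FALSE]
  prefs <- ifelse(pick_wide, pop$prefs[mo, , drop = FALSE],
                  pop$prefs[fa, , drop = FALSE])
  if (isTRUE(cfg$mutate_prefs)) {
    prefs <- prefs + stats::rnorm(n * p * k, 0, cfg$mutation_sd)
    ideal <- if (k == 1L) prefs else implied_ideal_all(prefs, pop$rule)
  } else {
    ideal <- ifelse(pick_p, pop$ideal[mo, , drop = FALSE],
                    pop$ideal[fa, , drop = FALSE])
  }

  gen <- pop$generation + 1L
  structure(list(
    id = sprintf("%s_g%d_a%d", pop$run_label, gen, seq_len(n)),
    sex = sample(rep(c("female", "male"), n / 2L)),
    traits = traits, prefs = prefs, ideal = ideal,
    energy = compute_energy(traits, pop$optimum),
    mate_id = rep(NA_character_, n),
    rule = pop$rule, k = k, n_traits = p,
    optimum = pop$optimum, generation = gen,
    seed = pop$seed, run_label = pop$run_label
  ), class = "mm_population")
}

# Mean scaled fulfillment of currently paired agents (both sexes).
.mean_fulfillment <- function(pop) {
  partner <- match(pop$mate_id, pop$id)
  paired <- which(!is.na(partner))
  if (!length(paired)) return(NA_real_)
  own <- .clamp(pop$ideal[paired, , drop = FALSE], 1, 7)
  other <- .clamp(pop$traits[partner[paired], , drop = FALSE], 1, 7)
  mean(scaled_distance(own, other))
}

#' Run one evolutionary market simulation
#'
#' Executes the full life cycle for `cfg$generations` generations:
#' attraction -> global min-max normalization -> pairing -> (preference
#' updating, in that null model) -> roulette-wheel reproduction -> death.
#' The returned final population is the last generation *at its pairing
#' phase*: preferences are those the agents actually used in choice, and
#' `mate_id` records that generation's matching, so the metric layer can
#' score fulfillment and mate values directly.
#'
#' @param cfg an `mm_config`.
#' @return an `mm_run`: list with `config`, `seed`, `summary` (one row per
#'   generation: `generation`, `mean_energy`, `mean_fulfillment`) and
#'   `final_population`.
#' @export
run_simulation <- function(cfg) {
  stopifnot(inherits(cfg, "mm_config"))
  pop <- init_population(cfg$n_agents, cfg$n_traits, cfg$rule, cfg$seed)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(substream_seed(cfg$seed, 7L))

  gens <- cfg$generations
  mean_energy <- numeric(gens); mean_fulfillment <- numeric(gens)
  final <- NULL

  for (g in seq_len(gens)) {
    idx_f <- which(pop$sex == "female"); idx_m <- which(pop$sex == "male")
    fa <- normalize_attraction(build_attraction_matrix(
      pop$prefs[idx_f, , drop = FALSE], pop$traits[idx_m, , drop = FALSE],
      cfg$rule))
    ma <- normalize_attraction(build_attraction_matrix(
      pop$prefs[idx_m, , drop = FALSE], pop$traits[idx_f, , drop = FALSE],
      cfg$rule))
    if (!is.null(cfg$search_k)) {
      rs <- restrict_search(fa, ma, cfg$search_k)
      fa <- rs$fa; ma <- rs$ma
    }
    matching <- switch(cfg$pairing,
      product = pair_by_mutual_attraction(fa, ma, "product"),
      minimum = pair_by_mutual_attraction(fa, ma, "minimum"),
      random = , pref_update = pair_randomly(length(idx_f), length(idx_m)))

    pop$mate_id[] <- NA_character_
    pf <- idx_f[matching$female]; pm <- idx_m[matching$male]
    pop$mate_id[pf] <- pop$id[pm]
    pop$mate_id[pm] <- pop$id[pf]

    mean_energy[g] <- mean(pop$energy)
    mean_fulfillment[g] <- .mean_fulfillment(pop)
    if (g == gens) final <- pop

    if (cfg$pairing == "pref_update") {
      frac <- cfg$update_fraction
      pop$prefs[pf, ] <- pop$prefs[pf, , drop = FALSE] +
        frac * (pop$traits[pm, , drop = FALSE] - pop$prefs[pf, , drop = FALSE])
      pop$prefs[pm, ] <- pop$prefs[pm, , drop = FALSE] +
        frac * (pop$traits[pf, , drop = FALSE] - pop$prefs[pm, , drop = FALSE])
      pop$ideal <- pop$prefs
    }
    if (g < gens) pop <- reproduce(matching, pop, cfg)
  }

  structure(list(config = cfg, seed = cfg$seed,
                 summary = data.frame(generation = seq_len(gens),
                                      mean_energy = mean_energy,
                                      mean_fulfillment = mean_fulfillment),
                 final_population = final),
            class = "mm_run")
}

#' @export
print.mm_run <- function(x, ...) {
  cat(sprintf(
    "<mm_run> rule '%s', pairing '%s', mu=%g, s=%g, %d generations, seed %d\n",
    x$config$rule, x$config$pairing, x$config$mutation_sd,
    x$config$selection_strength, x$config$generations, x$seed))
  cat(sprintf("  final mean energy %.3f, mean fulfillment %.3f\n",
              utils::tail(x$summary$mean_energy, 1),
              utils::tail(x$summary$mean_fulfillment, 1)))
  invisible(x)
}

#' Run a replicate sweep over the parameter grid
#'
#' Crosses mutation sds with selection strengths and runs `runs` seeded
#' replicates per setting. Every run gets an independent substream seed
#' derived deterministically from `base_cfg$seed` and its grid coordinates,
#' so the sweep can execute in any order (and resume) with identical results.
#' If `outdir` is given, each finished run is written immediately (final
#' population CSV + per-generation summary CSV) and runs whose artifacts
#' already exist are skipped.
#'
#' @param base_cfg an `mm_config` supplying everything but the grid.
#' @param mutation_sds,selection_strengths numeric grids.
#' @param runs replicates per setting (defaults to `base_cfg$runs`).
#' @param outdir optional output directory for incremental artifacts.
#' @return (invisibly, if `outdir` given) a named list of `mm_run` objects,
#'   names `<rule>.<pairing>_mu<mu>_s<s>_run<i>`.
#' @export
run_sweep <- function(base_cfg, mutation_sds = c(0.06, 0.15, 0.30),
                      selection_strengths = c(0.10, 0.15, 0.20),
                      runs = NULL, outdir = NULL) {
  stopifnot(inherits(base_cfg, "mm_config"))
  if (is.null(runs)) runs <- base_cfg$runs
  model_tag <- paste(base_cfg$rule, base_cfg$pairing, sep = ".")
  model_hash <- sum(utf8ToInt(model_tag))
  out <- list()
  for (mi in seq_along(mutation_sds)) {
    for (si in seq_along(selection_strengths)) {
      for (r in seq_len(runs)) {
        cfg <- base_cfg
        cfg$mutation_sd <- mutation_sds[mi]
        cfg$selection_strength <- selection_strengths[si]
        cfg$runs <- as.integer(runs)
        cfg$seed <- substream_seed(base_cfg$seed, model_hash, mi, si, r)
        tag <- sprintf("%s_mu%g_s%g_run%d", model_tag,
                       cfg$mutation_sd, cfg$selection_strength, r)
        if (!is.null(outdir)) {
          run_dir <- file.path(outdir, model_tag,
                               sprintf("%g_%g", cfg$mutation_sd,
                                       cfg$selection_strength),
                               sprintf("run_%d", r))
          pop_file <- file.path(run_dir, "population.csv")
          if (file.exists(pop_file)) next
          res <- run_simulation(cfg)
          dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
          write_population(res$final_population, pop_file)
          utils::write.csv(res$summary, file.path(run_dir, "summary.csv"),
                           row.names = FALSE)
          out[[tag]] <- res
        } else {
          out[[tag]] <- run_simulation(cfg)
        }
      }
    }
  }
  if (is.null(outdir)) out else invisible(out)
}
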