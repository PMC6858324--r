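#' Initialize a population of mating agents
#'
#' Creates a generation-0 population: half female, half male. Each agent
#' carries `n_traits` trait values drawn uniformly on \[1, 7\] (the Likert
#' range of the survey instrument the models mirror) and a preference block of
#' `n_traits * k` values drawn uniformly on \[-10, 10\], where `k` is the
#' preference-block width of the integration rule (see
#' [rule_pref_width()]). The deliberately wide preference range keeps starting
#' conditions equally uninformative for all integration rules. Each run also
#' draws a fixed "optimal" trait vector uniformly on \[1, 7\]; energy (the
#' fitness proxy) is inversely proportional to the summed deviation of traits
#' from this optimum (see [compute_energy()]).
#'
#' @param n_agents even positive integer; population size (default 200).
#' @param n_traits number of trait dimensions (default 20; use 5 to mirror
#'   the survey instrument).
#' @param rule integration-rule name: one of `"euclidean"`, `"cosine"`,
#'   `"aspiration"`, `"linear"`, `"curvilinear"`, `"polynomial"`, or a null
#'   model (`"random"`, `"pref_update"`, both of which carry Euclidean-style
#'   ideal-point preferences).
#' @param seed integer seed; identical seeds give bit-identical populations.
#' @param run_label optional label folded into agent ids.
#' @return an object of class `mm_population`.
#' @export
init_population <- function(n_agents = 200L, n_traits = 20L,
                            rule = "euclidean", seed = 1L,
                            run_label = NULL) {
  rule <- match.arg(rule, names(.RULES))
  if (length(n_agents) != 1L || n_agents < 2 || n_agents %% 2 != 0)
    stop("n_agents must be a positive even integer, got ", n_agents)
  n_agents <- as.integer(n_agents)
  n_traits <- as.integer(n_traits)
  k <- .RULES[[rule]]
  if (is.null(run_label)) run_label <- paste0("s", seed)

  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)

  traits <- matrix(stats::runif(n_agents * n_traits, 1, 7), n_agents, n_traits)
  prefs <- matrix(stats::runif(n_agents * n_traits * k, -10, 10),
                  n_agents, n_traits * k)
  optimum <- stats::runif(n_traits, 1, 7)
  sex <- sample(rep(c("female", "male"), n_agents / 2L))

  pop <- structure(list(
    id = sprintf("%s_g0_a%d", run_label, seq_len(n_agents)),
    sex = sex,
    traits = traits,
    prefs = prefs,
    ideal = NULL,
    energy = numeric(n_agents),
    mate_id = rep(NA_character_, n_agents),
    rule = rule, k = k, n_traits = n_traits,
    optimum = optimum,
    generation = 0L,
    seed = as.integer(seed),
    run_label = run_label
  ), class = "mm_population")
  pop$energy <- compute_energy(traits, optimum)
  pop$ideal <- implied_ideal_all(prefs, rule)
  pop
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' @export
print.mm_population <- function(x, ...) {
  cat(sprintf(
    "<mm_population> %d agents (%d female / %d male), %d traits, rule '%s', generation %d\n",
    length(x$id), sum(x$sex == "female"), sum(x$sex == "male"),
    x$n_traits, x$rule, x$generation))
  invisible(x)
}

#' Extract one agent from a population
#'
#' @param pop an `mm_population`.
#' @param i agent index.
#' @return a list with fields `id`, `sex`, `traits`, `preferences` (an
#'   `n_traits x k` matrix), `energy`, `mate_id`.
#' @export
get_agent <- function(pop, i) {
  stopifnot(inherits(pop, "mm_population"), i >= 1, i <= length(pop$id))
  list(id = pop$id[i], sex = pop$sex[i],
       traits = pop$traits[i, ],
       preferences = matrix(pop$prefs[i, ], nrow = pop$n_traits, ncol = pop$k,
                            byrow = TRUE),
       energy = pop$energy[i], mate_id = pop$mate_id[i])
}

.pref_colnames <- function(n_traits, k) {
  as.vector(t(outer(seq_len(n_traits), seq_len(k),
                    function(i, j) sprintf("pref_%d_%d", i, j))))
}

.fmt_num <- function(x) sprintf("%.17g", x)

#' Write / read a population as text
#'
#' `write_population()` writes one CSV row per agent (id, sex, traits, wide
#' preference columns, energy, mate_id) plus a JSON sidecar (`<path>.json`)
#' holding run metadata: rule, trait count, optimum vector, seed and
#' generation. Numeric values are written with 17 significant digits so the
#' round trip is bit-exact. `read_population()` validates column counts
#' against the declared rule and rebuilds the `mm_population`.
#'
#' @param pop an `mm_population`.
#' @param path CSV file path; the sidecar is written next to it.
#' @return `write_population()` returns `path` invisibly;
#'   `read_population()` returns an `mm_population`.
#' @export
write_population <- function(pop, path) {
  stopifnot(inherits(pop, "mm_population"))
  df <- data.frame(id = pop$id, sex = pop$sex, stringsAsFactors = FALSE)
  tr <- apply(pop$traits, 2, .fmt_num)
  if (is.null(dim(tr))) tr <- matrix(tr, nrow = 1L)
  colnames(tr) <- sprintf("trait_%d", seq_len(pop$n_traits))
  pr <- apply(pop$prefs, 2, .fmt_num)
  if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1L)
  colnames(pr) <- .pref_colnames(pop$n_traits, pop$k)
  df <- cbind(df, tr, pr)
  df$energy <- .fmt_num(pop$energy)
  df$mate_id <- pop$mate_id
  utils::write.csv(df, path, row.names = FALSE, na = "")
  meta <- list(rule = pop$rule, k = pop$k, n_traits = pop$n_traits,
               optimum = .fmt_num(pop$optimum), seed = pop$seed,
               generation = pop$generation, run_label = pop$run_label)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("metadata sidecar not found: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  for (f in c("rule", "n_traits", "optimum", "seed", "generation"))
    if (is.null(meta[[f]])) stop("metadata sidecar missing field '", f, "'")
  rule <- match.arg(meta$rule, names(.RULES))
  k <- .RULES[[rule]]
  n_traits <- as.integer(meta$n_traits)

  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  tcols <- grep("^trait_", names(df), value = TRUE)
  pcols <- grep("^pref_", names(df), value = TRUE)
  if (length(tcols) != n_traits)
    stop("expected ", n_traits, " trait columns, found ", length(tcols))
  if (length(pcols) != n_traits * k)
    stop("rule '", rule, "' requires ", n_traits * k,
         " preference columns, found ", length(pcols))
  bad <- which(!stats::complete.cases(df[c("id", "sex", tcols, pcols)]))
  if (length(bad)) stop("malformed row(s): ", paste(bad, collapse = ", "))

  n <- nrow(df)
  pop <- structure(list(
    id = df$id,
    sex = df$sex,
    traits = matrix(as.numeric(as.matrix(df[tcols])), n, n_traits),
    prefs = matrix(as.numeric(as.matrix(df[.pref_colnames(n_traits, k)])),
                   n, n_traits * k),
    ideal = NULL,
    energy = as.numeric(df$energy),
    mate_id = ifelse(df$mate_id == "" | is.na(df$mate_id),
                     NA_character_, df$mate_id),
    rule = rule, k = k, n_traits = n_traits,
    optimum = as.numeric(meta$optimum),
    generation = as.integer(meta$generation),
    seed = as.integer(meta$seed),
    run_label = if (is.null(meta$run_label)) "run" else meta$run_label
  ), class = "mm_population")
  if (length(pop$optimum) != n_traits)
    stop("sidecar optimum has length ", length(pop$optimum),
         ", expected ", n_traits)
  pop$ideal <- implied_ideal_all(pop$prefs, rule)
  pop
}
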