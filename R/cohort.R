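#' Specification for a synthetic cross-cultural cohort
#'
#' Defines the statistical structure of a generated survey table: one row per
#' respondent, with ideal-partner preferences, self ratings, and (for
#' partnered respondents) partner ratings on five 7-point scales, sampled per
#' country. Effect sizes are specified on the standardized (correlation)
#' scale in latent space; observed 1-7 ratings are the discretized latent
#' values, so recovered effects are mildly attenuated.
#'
#' Defaults emulate the structure of large cross-cultural mate-preference
#' surveys: 45 countries of ~322 respondents (~14.5k total), 63.75% of
#' respondents partnered, high mean fulfillment, and positive mate-value
#' gradients of roughly 0.26 (fulfillment), 0.38 (ideal standards) and 0.35
#' (assortative mating).
#'
#' @param n_countries number of countries.
#' @param n_per_country respondents per country.
#' @param partnered_fraction fraction of respondents in a relationship.
#' @param fulfillment_target mean scaled preference fulfillment (0-10).
#' @param fulfillment_sd total sd of fulfillment around its mean.
#' @param mv_fulfillment_slope,mv_ideal_slope,assortment_slope standardized
#'   mate-value gradients wired into the latent structure.
#' @param mean_mv,mv_sd latent mean and sd of overall mate value (0-10).
#' @param mean_ideal_mv,ideal_mv_sd latent mean and sd of ideal-partner mate
#'   value.
#' @param country_sd sd of country-level shifts of means (scaled units).
#' @param country_slope_sd sd of country-level slope heterogeneity.
#' @param report_noise_sd sd of the noise added to a partner's true traits
#'   when the respondent reports them.
#' @param mean_preferences length-`n_dims` profile of mean ideal ratings
#'   (recycled); people rate ideal partners well above the scale midpoint,
#'   but keeping the profile moderately below the ceiling limits how much
#'   the 1-7 clamp attenuates the wired-in effect sizes.
#' @param likert_bounds rating scale bounds (default `c(1, 7)`).
#' @param n_levels number of response categories (default 7).
#' @param n_dims preference dimensions (default 5).
#' @param seed integer seed.
#' @return an `mm_cohort_spec` list.
#' @export
cohort_spec <- function(n_countries = 45L, n_per_country = 322L,
                        partnered_fraction = 0.6375,
                        fulfillment_target = 8.3, fulfillment_sd = 0.8,
                        mv_fulfillment_slope = 0.26, mv_ideal_slope = 0.38,
                        assortment_slope = 0.35,
                        mean_mv = 7.8, mv_sd = 1.0,
                        mean_ideal_mv = 8.6, ideal_mv_sd = 0.7,
                        country_sd = 0.25, country_slope_sd = 0.08,
                        report_noise_sd = 0.25, likert_bounds = c(1, 7),
                        mean_preferences = c(5.4, 5.5, 5.2, 4.8, 4.5),
                        n_levels = 7L, n_dims = 5L, seed = 1L) {
  slopes <- c(mv_fulfillment_slope, mv_ideal_slope, assortment_slope)
  if (any(!is.finite(slopes)) || any(abs(slopes) > 1))
    stop("slopes must be finite standardized values in [-1, 1]")
  if (partnered_fraction < 0 || partnered_fraction > 1)
    stop("partnered_fraction must lie in [0, 1]")
  if (n_levels < 2) stop("n_levels must be at least 2")
  if (fulfillment_target >= 10 && fulfillment_sd > 0)
    warning("fulfillment_target at the scale ceiling with positive sd; ",
            "generation is best-effort")
  structure(as.list(environment())[setdiff(ls(), "slopes")],
            class = "mm_cohort_spec")
}

.discretize <- function(x, n_levels, bounds = c(1, 7)) {
  grid <- seq(bounds[1], bounds[2], length.out = n_levels)
  step <- grid[2] - grid[1]
  out <- grid[.clamp(round((x - bounds[1]) / step), 0, n_levels - 1) + 1]
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

.rand_unit <- function(d) {
  repeat {
    u <- stats::rnorm(d)
    n <- sqrt(sum(u^2))
    if (n > 1e-12) return(u / n)
  }
}

# A point x with ||x - c1|| = R1 and, where geometrically feasible,
# ||x - c2|| = R2 (sphere intersection); infeasible radii keep R1 exact and
# get as close to R2 as the triangle inequality allows.
.sphere_point <- function(c1, R1, c2, R2) {
  v <- c2 - c1
  dd <- sqrt(sum(v^2))
  if (dd < 1e-9) return(c1 + R1 * .rand_unit(length(c1)))
  u <- v / dd
  a <- .clamp((dd^2 + R1^2 - R2^2) / (2 * dd), -R1, R1)
  h <- sqrt(max(0, R1^2 - a^2))
  w <- stats::rnorm(length(c1))
  w <- w - sum(w * u) * u
  nw <- sqrt(sum(w^2))
  w <- if (nw > 1e-12) w / nw else 0 * w
  c1 + a * u + h * w
}

# Scaled value (0-10) -> Euclidean radius and back.
.mv_radius <- function(v, n_dims, rng = 6) (10 - v) / 10 * rng * sqrt(n_dims)

#' Generate a synthetic cross-cultural cohort table
#'
#' Latent-then-discretize generator. Per country, mean preference vectors for
#' each sex are drawn around a common profile; each respondent gets a latent
#' quality score that drives their mate value (own traits placed at the
#' corresponding Euclidean radius from the opposite sex's mean preferences),
#' their ideal standards (preferences placed at the ideal-mate-value radius
#' from the own-sex mean preferences), and — if partnered — their preference
#' fulfillment. Couples are matched on noisy quality ranks to produce the
#' requested assortative-mating correlation, and each partner's trait vector
#' is placed on the intersection of the two spheres fixing that partner's
#' mate value and the respondent's fulfillment. Latent values are then
#' rounded to the 1-7 grid; partner ratings are the partner's true latent
#' traits plus report noise.
#'
#' @param spec an `mm_cohort_spec`.
#' @return an `mm_cohort` data frame: `id`, `country`, `sex`, `couple`
#'   (`NA` if unpartnered), `pref_1..n`, `self_1..n`, `partner_1..n`
#'   (`NA` if unpartnered).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "mm_cohort_spec"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(spec$seed)

  d <- spec$n_dims
  base_pref <- rep_len(spec$mean_preferences, d)
  rows <- vector("list", spec$n_countries)

  for (ci in seq_len(spec$n_countries)) {
    country <- sprintf("C%02d", ci)
    m_pref <- list(
      female = base_pref + stats::rnorm(d, 0, spec$country_sd),
      male = base_pref + stats::rnorm(d, 0, spec$country_sd))
    b_f <- .clamp(spec$mv_fulfillment_slope +
                    stats::rnorm(1, 0, spec$country_slope_sd), -0.99, 0.99)
    b_i <- .clamp(spec$mv_ideal_slope +
                    stats::rnorm(1, 0, spec$country_slope_sd), -0.99, 0.99)
    b_a <- .clamp(spec$assortment_slope +
                    stats::rnorm(1, 0, spec$country_slope_sd), -0.99, 0.99)
    f_mean <- spec$fulfillment_target + stats::rnorm(1, 0, spec$country_sd)

    n <- spec$n_per_country
    n_f <- n %/% 2L; n_m <- n - n_f
    sex <- c(rep("female", n_f), rep("male", n_m))
    z <- stats::rnorm(n)
    mv <- .clamp(spec$mean_mv + spec$mv_sd * z, 0.2, 10)
    ideal_mv <- .clamp(spec$mean_ideal_mv + spec$ideal_mv_sd *
                         (b_i * z + sqrt(1 - b_i^2) * stats::rnorm(n)),
                       0.2, 10)
    # preferences: own ideal, at the choosiness radius from own-sex mean prefs
    # (female preferences live in male-trait space centred on m_pref$female)
    prefs <- t(vapply(seq_len(n), function(i) {
      m_pref[[sex[i]]] + .mv_radius(ideal_mv[i], d) * .rand_unit(d)
    }, numeric(d)))

    # couples: noisy-rank matching on latent quality gives the assortment r
    n_couples <- min(round(n * spec$partnered_fraction / 2), n_f, n_m)
    pf <- sample(which(sex == "female"), n_couples)
    pm <- sample(which(sex == "male"), n_couples)
    if (n_couples > 0 && b_a > 0) {
      noise_var <- 1 / b_a - 1
      pf <- pf[order(z[pf] + stats::rnorm(n_couples, 0, sqrt(noise_var)))]
      pm <- pm[order(z[pm] + stats::rnorm(n_couples, 0, sqrt(noise_var)))]
    }
    partner <- rep(NA_integer_, n)
    partner[pf] <- pm; partner[pm] <- pf
    fulfill <- .clamp(f_mean + spec$fulfillment_sd *
                        (b_f * z + sqrt(1 - b_f^2) * stats::rnorm(n)), 0, 10)

    # own traits: sphere around the opposite sex's mean preferences (radius =
    # own mate value), intersected with the sphere around the partner's
    # preference vector (radius = the partner's fulfillment)
    opp <- ifelse(sex == "female", "male", "female")
    traits <- matrix(NA_real_, n, d)
    for (i in seq_len(n)) {
      c1 <- m_pref[[opp[i]]]
      if (is.na(partner[i])) {
        traits[i, ] <- c1 + .mv_radius(mv[i], d) * .rand_unit(d)
      } else {
        j <- partner[i]
        traits[i, ] <- .sphere_point(c1, .mv_radius(mv[i], d),
                                     prefs[j, ], .mv_radius(fulfill[j], d))
      }
    }

    obs_pref <- .discretize(prefs, spec$n_levels, spec$likert_bounds)
    obs_self <- .discretize(traits, spec$n_levels, spec$likert_bounds)
    obs_partner <- matrix(NA_real_, n, d)
    ok <- !is.na(partner)
    obs_partner[ok, ] <- .discretize(
      traits[partner[ok], , drop = FALSE] +
        stats::rnorm(sum(ok) * d, 0, spec$report_noise_sd),
      spec$n_levels, spec$likert_bounds)

    couple <- rep(NA_character_, n)
    couple[pf] <- sprintf("%s_K%03d", country, seq_len(n_couples))
    couple[pm] <- couple[pf][match(partner[pm], pf)]

    df <- data.frame(id = sprintf("%s_r%04d", country, seq_len(n)),
                     country = country, sex = sex, couple = couple,
                     stringsAsFactors = FALSE)
    colnames(obs_pref) <- sprintf("pref_%d", seq_len(d))
    colnames(obs_self) <- sprintf("self_%d", seq_len(d))
    colnames(obs_partner) <- sprintf("partner_%d", seq_len(d))
    rows[[ci]] <- cbind(df, obs_pref, obs_self, obs_partner)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("mm_cohort", "data.frame")
  out
}

#' Validate a cohort table
#'
#' Checks column completeness, Likert bounds on all ratings, couple
#' bijectivity (each couple id links exactly one female and one male row),
#' and that partner ratings are present exactly for partnered rows.
#'
#' @param table a cohort data frame.
#' @return data frame of violations (`row`, `field`, `problem`); zero rows
#'   means the table is valid.
#' @export
validate_cohort <- function(table) {
  v <- list()
  add <- function(row, field, problem)
    v[[length(v) + 1L]] <<- data.frame(row = row, field = field,
                                       problem = problem,
                                       stringsAsFactors = FALSE)
  pref_cols <- grep("^pref_[0-9]+$", names(table), value = TRUE)
  self_cols <- grep("^self_[0-9]+$", names(table), value = TRUE)
  part_cols <- grep("^partner_[0-9]+$", names(table), value = TRUE)
  for (col in c("id", "country", "sex", "couple"))
    if (!col %in% names(table)) add(NA_integer_, col, "missing column")
  if (!length(pref_cols) || length(self_cols) != length(pref_cols) ||
      length(part_cols) != length(pref_cols))
    add(NA_integer_, "ratings", "pref_/self_/partner_ column sets mismatch")
  if (length(v)) return(do.call(rbind, v))

  for (col in c(pref_cols, self_cols, part_cols)) {
    bad <- which(!is.na(table[[col]]) &
                   (table[[col]] < 1 | table[[col]] > 7))
    for (r in bad) add(r, col, "rating outside [1, 7]")
  }
  partnered <- !is.na(table$couple)
  has_partner_rating <- !is.na(table[[part_cols[1]]])
  for (r in which(partnered != has_partner_rating))
    add(r, "partner ratings",
        "partner ratings must be present iff partnered")
  for (cid in unique(table$couple[partnered])) {
    members <- which(!is.na(table$couple) & table$couple == cid)
    if (length(members) != 2 ||
        sort(table$sex[members])[1] != "female" ||
        sort(table$sex[members])[2] != "male")
      add(members[1], "couple",
          sprintf("couple '%s' must link exactly one female and one male",
                  cid))
  }
  if (!length(v))
    return(data.frame(row = integer(0), field = character(0),
                      problem = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, v)
  rownames(out) <- NULL
  out
}
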