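#' Scaled Euclidean distance on the 0-10 mate-value scale
#'
#' `10 * (1 - ||a - b|| / (per_dim_range * sqrt(n)))`: 10 means the two
#' vectors are identical, 0 means they are as dissimilar as two points on the
#' trait scale can be (opposite corners of the \[1, 7\]^n cube when
#' `per_dim_range = 6`). Callers clamp inputs to the trait scale first so the
#' score stays in \[0, 10\].
#'
#' @param a,b numeric vectors of equal length, or matrices compared row by
#'   row.
#' @param per_dim_range width of the per-dimension scale (default 6, the 1-7
#'   Likert range).
#' @return scaled similarity value(s) in \[0, 10\] for in-scale inputs.
#' @export
scaled_distance <- function(a, b, per_dim_range = 6) {
  if (per_dim_range <= 0) stop("per_dim_range must be positive")
  a <- rbind(a); b <- rbind(b)
  if (!all(dim(a) == dim(b))) stop("a and b differ in shape")
  n <- ncol(a)
  if (n == 0) stop("vectors must have at least one dimension")
  d <- sqrt(rowSums((a - b)^2))
  unname(10 * (1 - d / (per_dim_range * sqrt(n))))
}

#' Preference fulfillment of one individual
#'
#' Scaled distance between an individual's (implied) ideal vector and the
#' actual partner's trait vector, both clamped to the trait scale. Missing
#' partner gives `NA`.
#'
#' @param ideal the individual's implied ideal trait vector (see
#'   [implied_ideal()]).
#' @param partner_traits the partner's trait vector, or `NULL`/all-`NA` if
#'   unpartnered.
#' @param likert_bounds trait scale (default `c(1, 7)`).
#' @return fulfillment in \[0, 10\], or `NA`.
#' @export
preference_fulfillment <- function(ideal, partner_traits,
                                   likert_bounds = c(1, 7)) {
  if (is.null(partner_traits) || all(is.na(partner_traits)))
    return(NA_real_)
  rng <- likert_bounds[2] - likert_bounds[1]
  scaled_distance(.clamp(ideal, likert_bounds[1], likert_bounds[2]),
                  .clamp(partner_traits, likert_bounds[1], likert_bounds[2]),
                  per_dim_range = rng)
}

#' Mean implied-ideal (preference) vector of one sex
#'
#' The group-level preference consensus used by all mate-value measures: the
#' arithmetic mean of the implied-ideal vectors of the named sex within the
#' group (a model run or a country), clamped to the trait scale.
#'
#' @param x an `mm_population` or a cohort table (see [generate_cohort()]).
#' @param sex `"female"` or `"male"`: whose preferences to average.
#' @param likert_bounds trait scale.
#' @return mean ideal vector.
#' @export
mean_opposite_preferences <- function(x, sex, likert_bounds = c(1, 7)) {
  parts <- .mv_parts(x)
  keep <- parts$sex == sex
  if (!any(keep)) stop("no agents of sex '", sex, "' in group")
  colMeans(.clamp(parts$ideal[keep, , drop = FALSE],
                  likert_bounds[1], likert_bounds[2]))
}

# Normalize populations and cohort tables to the shared representation the
# metric layer works on: implied ideals, own traits, partner traits, sex,
# group, id.
.mv_parts <- function(x) UseMethod(".mv_parts")

.mv_parts.mm_population <- function(x) {
  partner <- match(x$mate_id, x$id)
  pt <- matrix(NA_real_, length(x$id), x$n_traits)
  ok <- !is.na(partner)
  pt[ok, ] <- x$traits[partner[ok], , drop = FALSE]
  list(id = x$id, group = rep(x$run_label, length(x$id)), sex = x$sex,
       ideal = x$ideal, traits = x$traits, partner_traits = pt)
}

.mv_parts.data.frame <- function(x) {
  pref_cols <- grep("^pref_[0-9]+$", names(x), value = TRUE)
  self_cols <- grep("^self_[0-9]+$", names(x), value = TRUE)
  part_cols <- grep("^partner_[0-9]+$", names(x), value = TRUE)
  if (!length(pref_cols) || length(pref_cols) != length(self_cols) ||
      length(pref_cols) != length(part_cols))
    stop("cohort table must carry matching pref_*, self_* and partner_* ",
         "columns")
  list(id = as.character(x$id), group = as.character(x$country), sex = x$sex,
       ideal = as.matrix(x[pref_cols]), traits = as.matrix(x[self_cols]),
       partner_traits = as.matrix(x[part_cols]))
}

#' Mate-value suite: fulfillment and the three mate values
#'
#' Computes, for every agent of a simulated market or every respondent of a
#' survey-style cohort, the four scaled (0-10) Euclidean measures:
#' \describe{
#'   \item{fulfillment}{distance between own (implied) ideal and the actual
#'     partner's traits; `NA` if unpartnered.}
#'   \item{mate_value}{distance between own traits and the opposite sex's
#'     mean preference vector: how well one embodies what the other sex
#'     wants on average.}
#'   \item{ideal_mv}{"choosiness": the mate value of one's stated ideal,
#'     i.e. distance between own ideal vector and the mean preference vector
#'     of one's same-sex competitors.}
#'   \item{partner_mv}{the partner's mate value (their traits against the
#'     mean preferences of their opposite sex); `NA` if unpartnered.}
#' }
#' Group structure (model run or country) defines the mean preference
#' vectors. Agents and cohort rows go through the identical computation.
#'
#' @param x an `mm_population`, an `mm_run`, or a cohort table.
#' @param likert_bounds trait scale; all vectors are clamped to it first.
#' @return data frame with columns `id`, `group`, `sex`, `fulfillment`,
#'   `mate_value`, `ideal_mv`, `partner_mv`.
#' @export
mate_value_suite <- function(x, likert_bounds = c(1, 7)) {
  if (inherits(x, "mm_run")) x <- x$final_population
  parts <- .mv_parts(x)
  lo <- likert_bounds[1]; hi <- likert_bounds[2]; rng <- hi - lo
  ideal <- .clamp(parts$ideal, lo, hi)
  traits <- .clamp(parts$traits, lo, hi)
  ptraits <- .clamp(parts$partner_traits, lo, hi)
  n <- length(parts$id)
  out <- data.frame(id = parts$id, group = parts$group, sex = parts$sex,
                    fulfillment = NA_real_, mate_value = NA_real_,
                    ideal_mv = NA_real_, partner_mv = NA_real_,
                    stringsAsFactors = FALSE)
  for (g in unique(parts$group)) {
    gi <- which(parts$group == g)
    mean_pref <- list(
      female = colMeans(ideal[gi[parts$sex[gi] == "female"], , drop = FALSE]),
      male = colMeans(ideal[gi[parts$sex[gi] == "male"], , drop = FALSE]))
    opp <- ifelse(parts$sex[gi] == "female", "male", "female")
    mv_center <- do.call(rbind, mean_pref[opp])
    own_center <- do.call(rbind, mean_pref[parts$sex[gi]])
    out$mate_value[gi] <- scaled_distance(traits[gi, , drop = FALSE],
                                          mv_center, rng)
    out$ideal_mv[gi] <- scaled_distance(ideal[gi, , drop = FALSE],
                                        own_center, rng)
    paired <- gi[!is.na(ptraits[gi, 1])]
    if (length(paired)) {
      out$fulfillment[paired] <- scaled_distance(
        ideal[paired, , drop = FALSE], ptraits[paired, , drop = FALSE], rng)
      # partner's opposite sex == own sex, so the partner's mate value is
      # measured against the mean preferences of the respondent's own sex
      out$partner_mv[paired] <- scaled_distance(
        ptraits[paired, , drop = FALSE],
        do.call(rbind, mean_pref[parts$sex[paired]]), rng)
    }
  }
  out
}

.safe_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    return(NA_real_)
  stats::cor(x[ok], y[ok])
}

#' Power-of-choice summary statistics
#'
#' Within each group (model run or country), computes mean preference
#' fulfillment and the three Pearson correlations that quantify power of
#' choice on the mating market: mate value with fulfillment, mate value with
#' ideal-partner mate value (choosiness), and mate value with partner mate
#' value (assortative mating). Group-level values are then averaged, with a
#' t-based 95% confidence interval across groups. Groups where a correlation
#' is undefined (constant input) are reported `NA` with a warning and
#' excluded from that statistic's cross-group mean.
#'
#' @param records output of [mate_value_suite()], possibly row-bound across
#'   runs.
#' @param conf confidence level for the cross-group interval.
#' @return list with `by_group` (one row per group) and `summary` (one row
#'   per statistic: mean, sd, n_groups, ci_lo, ci_hi).
#' @export
power_of_choice_stats <- function(records, conf = 0.95) {
  groups <- unique(records$group)
  by_group <- do.call(rbind, lapply(groups, function(g) {
    r <- records[records$group == g, ]
    data.frame(group = g,
               mean_fulfillment = mean(r$fulfillment, na.rm = TRUE),
               r_mv_fulfillment = .safe_cor(r$mate_value, r$fulfillment),
               r_mv_ideal = .safe_cor(r$mate_value, r$ideal_mv),
               r_mv_partner = .safe_cor(r$mate_value, r$partner_mv),
               stringsAsFactors = FALSE)
  }))
  stats_cols <- c("mean_fulfillment", "r_mv_fulfillment", "r_mv_ideal",
                  "r_mv_partner")
  if (anyNA(by_group[stats_cols]))
    warning("some group-level statistics are undefined (constant input); ",
            "excluded from cross-group means")
  summary <- do.call(rbind, lapply(stats_cols, function(s) {
    v <- by_group[[s]]; v <- v[!is.na(v)]
    n <- length(v)
    m <- if (n) mean(v) else NA_real_
    sdv <- if (n > 1) stats::sd(v) else NA_real_
    half <- if (n > 1) stats::qt(1 - (1 - conf) / 2, n - 1) * sdv / sqrt(n)
            else NA_real_
    data.frame(statistic = s, mean = m, sd = sdv, n_groups = n,
               ci_lo = m - half, ci_hi = m + half, stringsAsFactors = FALSE)
  }))
  list(by_group = by_group, summary = summary)
}
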