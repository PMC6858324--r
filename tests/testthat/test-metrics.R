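test_that("scaled distance maps the trait cube onto the 0-10 scale", {
  expect_equal(scaled_distance(c(2, 5, 3), c(2, 5, 3)), 10)
  expect_equal(scaled_distance(rep(1, 4), rep(7, 4)), 0)
  expect_equal(scaled_distance(rep(4, 5), rep(5, 5)), 10 * 5 / 6)
  # strictly decreasing in the distance
  set.seed(3)
  a <- runif(6, 1, 7)
  steps <- seq(0, 3, 0.5)
  vals <- vapply(steps, function(d) scaled_distance(a, a + d / sqrt(6)),
                 numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_error(scaled_distance(numeric(0), numeric(0)), "dimension")
  expect_error(scaled_distance(1, 2, per_dim_range = 0), "positive")
})

test_that("preference fulfillment handles the worked examples and missing partners", {
  expect_equal(preference_fulfillment(c(3, 3), c(3, 3)), 10)
  expect_equal(preference_fulfillment(rep(7, 5), rep(1, 5)), 0)
  expect_equal(preference_fulfillment(rep(4, 5), rep(5, 5)), 10 * 5 / 6)
  expect_true(is.na(preference_fulfillment(rep(4, 5), NULL)))
  expect_true(is.na(preference_fulfillment(rep(4, 5), rep(NA_real_, 5))))
  # out-of-scale ideals are clamped to the instrument range first
  expect_equal(preference_fulfillment(c(-10, 9), c(1, 7)), 10)
})

test_that("mean preferences per sex are simple clamped averages", {
  pop <- make_toy_pop(rbind(c(4, 4), c(4, 4), c(4, 4)),
                      rbind(c(3, 3), c(5, 5), c(2, 6)),
                      c("female", "female", "male"))
  expect_equal(mean_opposite_preferences(pop, "female"), c(4, 4))
  expect_equal(mean_opposite_preferences(pop, "male"), c(2, 6))
  perm <- make_toy_pop(rbind(c(4, 4), c(4, 4), c(4, 4)),
                       rbind(c(5, 5), c(3, 3), c(2, 6)),
                       c("female", "female", "male"))
  expect_equal(mean_opposite_preferences(perm, "female"), c(4, 4))
})

test_that("the four-agent toy market matches the hand-computed score sheet", {
  pop <- make_toy_pop(
    traits = rbind(c(3, 4), c(5, 2), c(6, 5), c(4, 4)),
    prefs = rbind(c(5, 6), c(4, 4), c(2, 3), c(3, 5)),
    sex = c("female", "female", "male", "male"),
    mate_pairs = list(c(1, 3), c(2, 4)))
  rec <- mate_value_suite(pop)
  s2 <- 6 * sqrt(2)  # scale denominator for two 1-7 dimensions
  # mean prefs: female (4.5, 5); male (2.5, 4) -- hand averages
  expect_equal(rec$fulfillment,
               c(10 * (1 - sqrt(2) / s2), 10,
                 10 * (1 - sqrt(2) / s2), 10 * (1 - sqrt(13) / s2)))
  expect_equal(rec$mate_value,
               c(10 * (1 - 0.5 / s2), 10 * (1 - sqrt(10.25) / s2),
                 10 * (1 - 1.5 / s2), 10 * (1 - sqrt(1.25) / s2)))
  expect_equal(rec$ideal_mv, rep(10 * (1 - sqrt(1.25) / s2), 4))
  # partner mate value is the partner's own mate value
  expect_equal(rec$partner_mv, rec$mate_value[c(3, 4, 1, 2)])
})

test_that("unpartnered individuals keep mate values but lose dyadic scores", {
  pop <- make_toy_pop(rbind(c(3, 4), c(5, 2), c(6, 5), c(4, 4)),
                      rbind(c(5, 6), c(4, 4), c(2, 3), c(3, 5)),
                      c("female", "female", "male", "male"),
                      mate_pairs = list(c(1, 3)))
  rec <- mate_value_suite(pop)
  expect_true(is.na(rec$fulfillment[2]) && is.na(rec$partner_mv[2]))
  expect_false(anyNA(rec$mate_value) || anyNA(rec$ideal_mv))
})

test_that("power-of-choice statistics recover known correlation structure", {
  # degenerate: constant mate value
  const <- data.frame(id = 1:10, group = "g", sex = "female",
                      fulfillment = runif(10), mate_value = 5,
                      ideal_mv = runif(10), partner_mv = runif(10))
  expect_warning(st <- power_of_choice_stats(const), "undefined")
  expect_true(is.na(st$by_group$r_mv_fulfillment))

  # perfect alignment
  perfect <- data.frame(id = 1:50, group = "g", sex = "male",
                        fulfillment = 1:50, mate_value = 1:50,
                        ideal_mv = 50:1, partner_mv = 1:50)
  st <- power_of_choice_stats(perfect)$by_group
  expect_equal(st$r_mv_fulfillment, 1)
  expect_equal(st$r_mv_ideal, -1)

  # generator with slope 0.3 and unit noise: r = 0.3 / sqrt(1.09)
  set.seed(14)
  z <- rnorm(20000)
  gen <- data.frame(id = seq_along(z), group = "g", sex = "female",
                    fulfillment = 0.3 * z + rnorm(length(z)),
                    mate_value = z, ideal_mv = 5, partner_mv = 5)
  # the constant ideal/partner columns warn (undefined r), by design
  st <- suppressWarnings(power_of_choice_stats(gen))$by_group
  expect_equal(st$r_mv_fulfillment, 0.3 / sqrt(1.09), tolerance = 0.03)

  # cross-group summary carries t-based intervals
  two <- rbind(transform(perfect, group = "a"), transform(perfect, group = "b"))
  sm <- power_of_choice_stats(two)$summary
  expect_equal(sm$n_groups, rep(2L, 4))
  expect_true(all(sm$ci_lo <= sm$mean & sm$mean <= sm$ci_hi))
})

test_that("within-group standardization leaves the correlations unchanged", {
  set.seed(31)
  rec <- data.frame(id = 1:200, group = rep(c("a", "b"), each = 100),
                    sex = "female",
                    fulfillment = runif(200, 0, 10),
                    mate_value = runif(200, 0, 10),
                    ideal_mv = runif(200, 0, 10),
                    partner_mv = runif(200, 0, 10))
  std <- rec
  for (g in c("a", "b")) {
    i <- std$group == g
    for (col in c("fulfillment", "mate_value", "ideal_mv", "partner_mv"))
      std[[col]][i] <- as.numeric(scale(std[[col]][i]))
  }
  a <- power_of_choice_stats(rec)$by_group
  b <- power_of_choice_stats(std)$by_group
  cols <- c("r_mv_fulfillment", "r_mv_ideal", "r_mv_partner")
  expect_equal(a[cols], b[cols])
})

test_that("agents and cohort rows share one metric code path", {
  set.seed(77)
  n <- 12
  traits <- matrix(round(runif(n * 5, 1, 7)), n, 5)
  prefs <- matrix(round(runif(n * 5, 1, 7)), n, 5)
  sex <- rep(c("female", "male"), each = n / 2)
  pairs <- lapply(1:3, function(i) c(i, i + n / 2))
  pop <- make_toy_pop(traits, prefs, sex, mate_pairs = pairs)
  partner <- match(pop$mate_id, pop$id)
  ptr <- matrix(NA_real_, n, 5)
  ptr[!is.na(partner), ] <- traits[partner[!is.na(partner)], ]
  cohort <- data.frame(id = pop$id, country = "toy", sex = sex,
                       couple = ifelse(is.na(partner), NA,
                                       paste0("k", pmin(seq_len(n), partner))))
  colnames(prefs) <- paste0("pref_", 1:5)
  colnames(traits) <- paste0("self_", 1:5)
  colnames(ptr) <- paste0("partner_", 1:5)
  cohort <- cbind(cohort, prefs, traits, ptr)
  a <- mate_value_suite(pop)
  b <- mate_value_suite(cohort)
  for (col in c("fulfillment", "mate_value", "ideal_mv", "partner_mv"))
    expect_equal(a[[col]], b[[col]], label = col)
})
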