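make_records <- function(n, slope = c(f = 0.3, i = 0.4, p = 0.2),
                         noise = 1, group = "g", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mv <- runif(n, 2, 9)
  data.frame(id = paste0(group, "_", seq_len(n)), group = group,
             sex = rep(c("female", "male"), length.out = n),
             fulfillment = 5 + slope[["f"]] * mv + rnorm(n, 0, noise),
             mate_value = mv,
             ideal_mv = 4 + slope[["i"]] * mv + rnorm(n, 0, noise),
             partner_mv = 6 + slope[["p"]] * mv + rnorm(n, 0, noise),
             stringsAsFactors = FALSE)
}

test_that("long-table reshaping counts rows per observed outcome", {
  rec <- make_records(10, seed = 1)
  long <- to_long(rec)
  expect_equal(nrow(long), 30L)
  rec$fulfillment[1] <- NA; rec$partner_mv[1] <- NA  # unpartnered
  long <- to_long(rec)
  expect_equal(nrow(long), 28L)
  expect_equal(sum(long$id == rec$id[1]), 1L)
  expect_equal(as.character(unique(long$outcome_type[long$id == rec$id[1]])),
               "ideal_mv")
  # round trip: values survive the reshape
  for (ot in c("fulfillment", "ideal_mv", "partner_mv")) {
    sub <- long[long$outcome_type == ot, ]
    expect_equal(sub$outcome_value, rec[[ot]][match(sub$id, rec$id)])
  }
})

test_that("the predictor recovers a noiseless linear structure exactly", {
  rec <- make_records(40, noise = 0, seed = 2)
  fit <- train_predictor(to_long(rec))
  cf <- fit$coefficients
  expect_equal(cf[["(Intercept)"]], 5, tolerance = 1e-8)
  expect_equal(cf[["mate_value"]], 0.3, tolerance = 1e-8)
  expect_equal(cf[["outcome_typeideal_mv"]], -1, tolerance = 1e-8)
  expect_equal(cf[["mate_value:outcome_typeideal_mv"]], 0.1, tolerance = 1e-8)
  expect_equal(cf[["outcome_typepartner_mv"]], 1, tolerance = 1e-8)
  expect_equal(cf[["mate_value:outcome_typepartner_mv"]], -0.1,
               tolerance = 1e-8)
  # linear-predictor identity
  nd <- data.frame(mate_value = 5, outcome_type = "fulfillment")
  expect_equal(predict(fit, nd), 5 + 5 * 0.3, tolerance = 1e-8)
  nd2 <- data.frame(mate_value = 5, outcome_type = "ideal_mv")
  expect_equal(predict(fit, nd2), 5 - 1 + 5 * (0.3 + 0.1), tolerance = 1e-8)
  expect_error(train_predictor(to_long(rec)[1:5, ]), "outcome types|individuals")
})

test_that("the mixed model recovers slopes with random intercepts present", {
  set.seed(3)
  n <- 200
  mv <- runif(n, 2, 9)
  ri <- rnorm(n, 0, 1)
  long <- do.call(rbind, lapply(c("fulfillment", "ideal_mv", "partner_mv"),
    function(ot) data.frame(id = seq_len(n), group = "g", mate_value = mv,
                            outcome_type = ot,
                            outcome_value = 2 + 0.3 * mv + ri +
                              rnorm(n, 0, 0.4))))
  fit <- train_predictor(long)
  expect_false(fit$fallback)
  expect_lt(abs(fit$coefficients[["mate_value"]] - 0.3), 0.12)
})

test_that("out-of-sample scores follow the textbook definitions", {
  rec <- make_records(30, noise = 0, seed = 4)
  long <- to_long(rec)
  fit <- train_predictor(long)
  sc <- score_out_of_sample(fit, long)   # noiseless: perfect in-sample fit
  expect_equal(sc$rmse, 0, tolerance = 1e-7)
  expect_equal(sc$correlation, 1, tolerance = 1e-7)

  shifted <- long; shifted$outcome_value <- shifted$outcome_value + 1
  sc <- score_out_of_sample(fit, shifted)
  expect_equal(sc$rmse, 1, tolerance = 1e-7)
  expect_equal(sc$correlation, 1, tolerance = 1e-7)

  # observed (1,2,3) vs predicted (1,2,5): RMSE = sqrt(4/3) by hand
  ident <- structure(list(coefficients = c("(Intercept)" = 0,
                                           "mate_value" = 1),
                          types = c("fulfillment", "ideal_mv"),
                          std_slopes = NULL, fallback = TRUE),
                     class = "mm_predictor")
  cl <- data.frame(id = 1:3, group = "g", mate_value = c(1, 2, 5),
                   outcome_type = "fulfillment", outcome_value = c(1, 2, 3))
  sc <- score_out_of_sample(ident, cl)
  expect_equal(sc$rmse, sqrt(4 / 3))
  expect_equal(sc$correlation, cor(c(1, 2, 5), c(1, 2, 3)))

  # random data: agree with direct formulas on the predictions themselves
  rnd <- make_records(50, seed = 5)
  fit <- train_predictor(to_long(rnd))
  cl <- to_long(make_records(50, seed = 6))
  sc <- score_out_of_sample(fit, cl)
  pred <- predict(fit, cl)
  expect_equal(sc$rmse, sqrt(mean((pred - cl$outcome_value)^2)))
  expect_equal(sc$correlation, cor(pred, cl$outcome_value))
  expect_error(score_out_of_sample(fit, cl[0, ]), "empty")

  flat <- structure(list(coefficients = c("(Intercept)" = 2,
                                          "mate_value" = 0),
                         types = "fulfillment", std_slopes = NULL,
                         fallback = TRUE), class = "mm_predictor")
  expect_true(is.na(score_out_of_sample(flat, cl[cl$outcome_type ==
                                                   "fulfillment", ])$correlation))
})

test_that("model comparison aggregates runs and the cohort baseline wins in-sample", {
  cohort <- make_records(300, group = "cohort", seed = 7)
  runs_a <- lapply(1:4, function(i) make_records(150, group = paste0("a", i),
                                                 seed = 10 + i))
  runs_b <- lapply(1:4, function(i)
    make_records(150, slope = c(f = -0.3, i = -0.4, p = -0.2),
                 group = paste0("b", i), seed = 20 + i))
  rep1 <- compare_models(list(aligned = runs_a, reversed = runs_b), cohort)
  rep2 <- compare_models(list(aligned = runs_a, reversed = runs_b), cohort)
  expect_identical(rep1, rep2)
  expect_s3_class(rep1, "mm_fitreport")
  expect_equal(nrow(rep1), 3L)
  base <- rep1[rep1$baseline, ]
  others <- rep1[!rep1$baseline, ]
  expect_true(all(base$rmse_mean <= others$rmse_mean))
  al <- rep1[rep1$model == "aligned", ]
  rv <- rep1[rep1$model == "reversed", ]
  expect_gt(al$cor_mean, rv$cor_mean)   # gradient direction transfers
  expect_true(all(al$cor_lo <= al$cor_mean & al$cor_mean <= al$cor_hi))
})

test_that("confidence intervals shrink roughly as one over sqrt(runs)", {
  # batch-averaged CI widths tame the chi-square noise of per-batch run sds
  mk <- function(n_runs, seed0)
    lapply(seq_len(n_runs), function(i)
      make_records(30, group = paste0("r", i), seed = seed0 + i))
  cohort <- make_records(200, group = "cohort", seed = 99)
  width <- function(n_runs, seed0) {
    rep <- compare_models(list(m = mk(n_runs, seed0)), cohort,
                          include_baseline = FALSE)
    rep$rmse_hi - rep$rmse_lo
  }
  w_small <- mean(vapply(1:6, function(b) width(8, 1000 * b), numeric(1)))
  w_big <- mean(vapply(1:6, function(b) width(32, 50000 + 1000 * b),
                       numeric(1)))
  expect_gt(w_small, w_big)
  expect_gt(w_small / w_big, 1.3)   # expected factor 2 for a 4x run count
  expect_lt(w_small / w_big, 3.1)
})
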