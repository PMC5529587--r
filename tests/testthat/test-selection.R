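test_that("AICc formula and limits", {
  expect_equal(aicc(-10, 2, 10), 24 + 12 / 7)
  # large-n limit approaches plain AIC
  expect_equal(aicc(-10, 2, 1e9), 24, tolerance = 1e-6)
  expect_error(aicc(-10, 5, 6), "undefined")
  # double-entry check on random triples
  set.seed(2)
  for (i in 1:100) {
    ll <- stats::rnorm(1, -50, 20); k <- sample(1:6, 1); n <- k + 2 + sample(50, 1)
    expect_equal(aicc(ll, k, n),
                 -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1))
  }
})

test_that("Akaike weights and RVI additivity", {
  w <- weights_and_rvi(c(100, 102), matrix(c(TRUE, FALSE), 2, 1,
                                           dimnames = list(NULL, "x")))
  expect_equal(sum(w$weights), 1)
  expect_equal(w$weights, c(1 / (1 + exp(-1)), exp(-1) / (1 + exp(-1))),
               tolerance = 1e-12)
  # models {x}, {y}, {x,y} with weights 0.5/0.3/0.2: RVI(x) = 0.7
  mem <- rbind(c(TRUE, FALSE), c(FALSE, TRUE), c(TRUE, TRUE))
  colnames(mem) <- c("x", "y")
  a <- -2 * log(c(0.5, 0.3, 0.2))  # aicc values reproducing these weights
  wr <- weights_and_rvi(a, mem)
  expect_equal(unname(wr$rvi["x"]), 0.7, tolerance = 1e-12)
  # variable in every model has RVI 1
  wr2 <- weights_and_rvi(c(10, 12), matrix(TRUE, 2, 1,
                                           dimnames = list(NULL, "z")))
  expect_equal(unname(wr2$rvi["z"]), 1)
  # shift invariance
  wr3 <- weights_and_rvi(a + 1000, mem)
  expect_equal(wr3$rvi, wr$rvi)
})

test_that("all-subsets enumeration covers every subset including the null model", {
  set.seed(4)
  d <- data.frame(y = rnorm(40), x1 = rnorm(40), x2 = rnorm(40))
  cs <- all_subsets_fit(d, "y", c("x1", "x2"))
  expect_equal(length(cs$models), 4)
  expect_equal(sum(rowSums(cs$membership) == 0), 1)
  expect_true(all(is.finite(cs$aicc)))
  # weights over all models sum to one
  expect_equal(sum(weights_and_rvi(cs$aicc, cs$membership)$weights), 1,
               tolerance = 1e-12)
  expect_error(all_subsets_fit(d, "y", rep("x1", 11)), "larger than 10")
})

test_that("lm backend matches stats::lm coefficients, SEs and logLik", {
  set.seed(8)
  d <- data.frame(y = rnorm(60), a = rnorm(60), b = rnorm(60))
  cs <- all_subsets_fit(d, "y", c("a", "b"))
  full <- cs$models[[4]]
  ref <- stats::lm(y ~ a + b, data = d)
  expect_equal(unname(full$coef), unname(coef(ref)), tolerance = 1e-10)
  expect_equal(unname(sqrt(full$var)),
               unname(sqrt(diag(stats::vcov(ref)))), tolerance = 1e-10)
  expect_equal(full$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-8)
  expect_equal(full$k, attr(stats::logLik(ref), "df"))
})

test_that("best-AICc model finds a strong true predictor", {
  set.seed(31)
  hits <- 0
  for (r in 1:100) {
    n <- 200
    d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
    d$y <- 1 * d$x1 + rnorm(n, 0, 0.5)
    cs <- all_subsets_fit(d, "y", c("x1", "x2", "x3"))
    best <- which.min(cs$aicc)
    if (cs$membership[best, "x1"]) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("full model averaging reproduces the closed-form example", {
  # two models, weights 0.5/0.5; beta present (1, var 0.04) vs absent
  cs <- structure(list(
    models = list(list(loglik = -1, k = 2, coef = c(`(Intercept)` = 0, x = 1),
                       var = c(`(Intercept)` = 0, x = 0.04), converged = TRUE),
                  list(loglik = -1, k = 1, coef = c(`(Intercept)` = 0),
                       var = c(`(Intercept)` = 0), converged = TRUE)),
    membership = matrix(c(TRUE, FALSE), 2, 1, dimnames = list(NULL, "x")),
    aicc = c(10, 10), n = 50, pool = "x", response = "y", backend = "lm",
    excluded = 0L), class = "candidate_set")
  avg <- model_average(cs)
  row <- avg[avg$variable == "x", ]
  expect_equal(row$estimate, 0.5)
  expect_equal(row$adjusted_se, sqrt(0.5 * (0.04 + 0.25) + 0.5 * 0.25),
               tolerance = 1e-12)
  expect_equal(row$rvi, 0.5)
  # single-model degenerate case: averaged = its own estimate and SE
  cs1 <- cs; cs1$aicc <- c(10, Inf)
  avg1 <- model_average(cs1, weights = c(1, 0))
  expect_equal(avg1$estimate[avg1$variable == "x"], 1)
  expect_equal(avg1$adjusted_se[avg1$variable == "x"], 0.2)
})

test_that("iterative rotation keeps RVI > 0.5 variables and terminates", {
  set.seed(12)
  n <- 150
  d <- as.data.frame(matrix(rnorm(n * 15), n))
  names(d) <- paste0("v", 1:15)
  d$y <- 1.2 * d$v1 + 1.0 * d$v12 + rnorm(n, 0, 0.7)
  sel <- iterative_rvi_selection(d, "y", paste0("v", 1:15))
  expect_lte(length(sel$rounds), 3)
  expect_true(all(c("v1", "v12") %in% sel$final_pool))
  # every reported non-intercept variable passed the keep threshold
  final_rvi <- sel$table$rvi[!is.na(sel$table$rvi)]
  expect_true(all(sel$table$variable[-1] %in% sel$final_pool))
  # ten or fewer variables: single round
  sel2 <- iterative_rvi_selection(d, "y", paste0("v", 1:8))
  expect_equal(length(sel2$rounds), 1)
})

test_that("clutch aggregation averages all variables and keeps accounting", {
  tab <- data.frame(id = 1:6, clutch_id = c("c1", "c1", "c1", "c1", "c2", "c2"),
                    aviary = 1, mother = "F1",
                    y = c(1, 1, 0, 1, 1, 0),
                    sex = c(1, 0, 1, 1, 1, 0))
  attr(tab, "predictors") <- "sex"
  agg <- aggregate_by_clutch(tab)
  expect_equal(nrow(agg), 2)
  expect_equal(agg$y[agg$clutch_id == "c1"], 0.75)
  expect_equal(agg$sex[agg$clutch_id == "c2"], 0.5)
  expect_equal(sum(agg$n_in_clutch), nrow(tab))
})

test_that("significance markers switch at the conventional thresholds", {
  expect_equal(mhcnest:::signif_marker(c(0.049, 0.051, 0.009, 0.0009, 0.2)),
               c("*", ".", "**", "***", ""))
})

test_that("selection result tables round-trip through TSV", {
  set.seed(9)
  d <- data.frame(y = rnorm(50), x = rnorm(50))
  sel <- iterative_rvi_selection(d, "y", "x")
  dir <- withr::local_tempdir()
  paths <- report_tables(list(resp = sel), dir)
  back <- utils::read.delim(file.path(dir, "selection_resp.tsv"))
  expect_equal(back$estimate, sel$table$estimate, tolerance = 1e-12)
  expect_equal(back$variable, sel$table$variable)
})

test_that("lmer backend produces comparable fits behind the same contract", {
  set.seed(21)
  n <- 120
  d <- data.frame(x = rnorm(n),
                  aviary = rep(1:6, each = 20),
                  female = rep(1:12, each = 10))
  d$y <- 0.8 * d$x + rnorm(6)[d$aviary] * 0.3 + rnorm(n, 0, 0.6)
  cs <- all_subsets_fit(d, "y", "x", backend = "lmer",
                        random = "(1 | aviary/female)")
  expect_equal(length(cs$models), 2)
  full <- cs$models[[2]]
  expect_true(full$converged)
  expect_true(full$k > 3)  # fixed effects + 2 variance components + residual
  expect_equal(unname(full$coef["x"]), 0.8, tolerance = 0.2)
})
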