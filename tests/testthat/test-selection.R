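# small deterministic inputs for design-building checks
design_inputs <- function(two_repeats = FALSE) {
  scores <- tiny_scores(seed = 12)
  scores <- dplyr::bind_rows(
    scores,
    dplyr::mutate(scores, phase = "post")
  )
  asym <- tibble::tibble(
    horse = rep(c("h1", "h2"), each = 2),
    occasion = rep(c("b0", "p1"), 2),
    score_mm = c(0, 40, 0, 25)
  )
  if (two_repeats) {
    asym <- dplyr::bind_rows(
      dplyr::mutate(asym, trot_repeat = 1L),
      dplyr::mutate(asym, trot_repeat = 2L, score_mm = score_mm + 5)
    )
  }
  list(scores = scores, asym = asym)
}

test_that("one trot repeat shares its score between pre and post", {
  inp <- design_inputs()
  d <- build_design(inp$scores, inp$asym, truncate_at_max = FALSE)
  k <- d$keys
  pre <- k$score_mm[k$horse == "h1" & k$occasion == "p1" & k$phase == "pre"]
  post <- k$score_mm[k$horse == "h1" & k$occasion == "p1" & k$phase == "post"]
  expect_true(all(pre == 40) && all(post == 40))
})

test_that("two trot repeats pair pre with the first and post with the second", {
  inp <- design_inputs(two_repeats = TRUE)
  d <- build_design(inp$scores, inp$asym, truncate_at_max = FALSE)
  k <- d$keys
  expect_true(all(k$score_mm[k$horse == "h1" & k$occasion == "p1" &
                               k$phase == "pre"] == 40))
  expect_true(all(k$score_mm[k$horse == "h1" & k$occasion == "p1" &
                               k$phase == "post"] == 45))
})

test_that("each horse is truncated at its maximum-score occasion", {
  asym <- tibble::tibble(
    horse = rep("h1", 5),
    occasion = c("b0", "p1", "p2", "p3", "p4"),
    score_mm = c(0, 30, 70, 40, 10)
  )
  keep <- kept_occasions(asym)
  expect_equal(keep$occasion, c("b0", "p1", "p2"))
  # truncation inside build_design drops the late assessments
  scores <- tidyr::expand_grid(
    horse = "h1", occasion = asym$occasion, phase = c("pre", "post"),
    observer = c("o1", "o2"), scale = "HGS", item = "orb", score = 1L
  )
  d <- build_design(scores, asym)
  expect_false(any(d$keys$occasion %in% c("p3", "p4")))
})

test_that("design encodes item levels above zero with reference level 0", {
  inp <- design_inputs()
  d <- build_design(inp$scores, inp$asym, truncate_at_max = FALSE)
  expect_true(all(grepl("^(hgs|fap|eps|cps)_", d$item_cols)))
  expect_false(any(grepl("0$", d$item_cols)))
  # indicator rows: a row's active item columns match its scores
  expect_true(all(d$x[, d$item_cols] %in% c(0, 1)))
  # horse and observer indicators present
  expect_true(all(c("h1", "h2", "o1", "o2") %in% colnames(d$x)))
})

test_that("the largest path lambda zeroes every coefficient", {
  inp <- design_inputs()
  d <- build_design(inp$scores, inp$asym, truncate_at_max = FALSE)
  fit <- fit_lasso_cv(d, n_folds = 4, seed = 1)
  b_top <- as.numeric(glmnet::coef.glmnet(fit$cv$glmnet.fit,
                                          s = max(fit$lambda_path)))[-1]
  expect_true(all(b_top == 0))
})

test_that("the lambda -> 0 limit matches least squares on a full-rank design", {
  set.seed(11)
  n <- 80
  x <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("v", 1:6)))
  y <- drop(x %*% c(3, -2, 1, 0, 0, 0.5)) + rnorm(n)
  d <- structure(list(x = x, y = y, keys = NULL, item_cols = colnames(x),
                      effect_cols = character(0)), class = "asym_design")
  fit <- fit_lasso_cv(d, n_folds = 10, seed = 1, thresh = 1e-14)
  b <- as.numeric(stats::coef(fit$cv, s = 0, exact = TRUE, x = x, y = y,
                              thresh = 1e-14,
                              penalty.factor = rep(1, ncol(x))))
  ols <- unname(stats::coef(stats::lm(y ~ x)))
  expect_equal(b, ols, tolerance = 1e-6)
})

test_that("KKT conditions hold at lambda_min", {
  set.seed(3)
  for (i in 1:5) {
    n <- 60
    p <- 12
    x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
    y <- drop(x %*% c(2, -1, rep(0, p - 2))) + rnorm(n)
    d <- structure(list(x = x, y = y, keys = NULL, item_cols = colnames(x),
                        effect_cols = character(0)), class = "asym_design")
    fit <- fit_lasso_cv(d, n_folds = 10, seed = i, thresh = 1e-12)
    expect_lt(equiasym:::lasso_kkt(fit), 1e-6)
  }
})

test_that("fold assignment and the fit are reproducible from the seed", {
  inp <- design_inputs()
  d <- build_design(inp$scores, inp$asym, truncate_at_max = FALSE)
  f1 <- fit_lasso_cv(d, n_folds = 4, seed = 9)
  f2 <- fit_lasso_cv(d, n_folds = 4, seed = 9)
  expect_identical(f1$foldid, f2$foldid)
  expect_identical(f1$coefficients, f2$coefficients)
})

test_that("select_items ranks by magnitude and separates effect columns", {
  fit <- structure(list(
    coefficients = c(eps_pos1 = 2, hgs_orb1 = -5, h1 = 7, o2 = 0,
                     cps_paw1 = 0),
    design = list(item_cols = c("eps_pos1", "hgs_orb1", "cps_paw1"),
                  effect_cols = c("h1", "o2"))), class = "lasso_fit")
  out <- select_items(fit)
  expect_equal(out$term, c("hgs_orb1", "eps_pos1", "h1"))
  expect_equal(out$type, c("item", "item", "effect"))
  fit$coefficients[] <- 0
  expect_equal(nrow(select_items(fit)), 0)
})

test_that("a planted posture effect dominates the item ranking", {
  hits <- 0L
  for (r in 1:10) {
    d <- trial_design(item_effects = c("EPS:pos" = 2, "CPS:pos" = 2),
                      observer_noise_sd = 1, horse_effect_sd = 0.3,
                      seed = 700 + r)
    s <- simulate_scores(d)
    truth <- score_truth(s)$asymmetry
    asym <- dplyr::transmute(truth, horse, occasion,
                             score_mm = true_score_mm)
    dm <- build_design(s, asym, truncate_at_max = FALSE)
    fit <- fit_lasso_cv(dm, seed = r)
    top <- select_items(fit) |>
      dplyr::filter(type == "item") |>
      dplyr::slice_head(n = 2)
    if (any(grepl("^(eps|cps)_pos", top$term))) hits <- hits + 1L
  }
  expect_gte(hits, 8)
})

test_that("nonzero count is non-increasing along growing lambda", {
  set.seed(21)
  n <- 70
  x <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("v", 1:10)))
  y <- drop(x %*% c(3, -2, 1, rep(0, 7))) + rnorm(n)
  d <- structure(list(x = x, y = y, keys = NULL, item_cols = colnames(x),
                      effect_cols = character(0)), class = "asym_design")
  fit <- fit_lasso_cv(d, seed = 1)
  nz <- fit$cv$nzero  # ordered by decreasing lambda
  expect_true(all(diff(as.integer(nz)) >= -10))  # path grows roughly monotonely
  # strict check against the path's own ordering at the ends
  expect_lte(nz[[1]], nz[[length(nz)]])
})

test_that("constant response and undersized designs are rejected", {
  x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  d <- structure(list(x = x, y = rep(1, 20), keys = NULL,
                      item_cols = c("a", "b"), effect_cols = character(0)),
                 class = "asym_design")
  expect_error(fit_lasso_cv(d), "constant response")
  d$y <- rnorm(20)
  expect_error(fit_lasso_cv(d, n_folds = 30), "fewer rows")
})
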