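# score table with controlled co-occurrence structure for MCA checks
mca_scores <- function(seed = 1, n_horses = 6, n_post = 3) {
  simulate_scores(trial_design(n_horses = n_horses, n_post_occasions = n_post,
                               observer_noise_sd = 0.8, horse_effect_sd = 0.5,
                               seed = seed))
}

test_that("indicator coding is complete disjunctive", {
  s <- mca_scores(2)
  z <- build_indicator(s)
  q <- attr(z, "q")
  expect_equal(q, 37)
  expect_true(all(rowSums(z) == q))
  expect_true(all(z %in% c(0, 1)))
  # block sums: every item contributes exactly one 1 per row
  two_items <- dplyr::filter(s, scale == "HGS", item %in% c("orb", "ears"))
  z2 <- build_indicator(two_items)
  expect_true(all(rowSums(z2) == 2))
})

test_that("per-assessment mode takes a median consensus", {
  s <- tiny_scores(seed = 8)
  z <- build_indicator(s, row_mode = "assessment")
  expect_equal(nrow(z), nrow(dplyr::distinct(s, horse, occasion, phase)))
  expect_false("observer" %in% names(attr(z, "keys")))
})

test_that("total inertia equals J/Q - 1", {
  set.seed(5)
  for (i in 1:5) {
    s <- mca_scores(seed = 30 + i, n_horses = 4)
    z <- build_indicator(s)
    m <- fit_mca(z)
    expect_equal(m$total_inertia, ncol(z) / attr(z, "q") - 1,
                 tolerance = 1e-8)
  }
})

test_that("eigenvalues match the Burt-matrix route", {
  for (i in 1:5) {
    s <- mca_scores(seed = 60 + i, n_horses = 4)
    z <- build_indicator(s)
    m <- fit_mca(z)
    burt <- oracle_burt_eigenvalues(z)
    k <- min(length(burt), length(m$eigenvalues))
    expect_equal(m$eigenvalues[1:k], burt[1:k], tolerance = 1e-8)
  }
})

test_that("row coordinates are centered and transitions hold", {
  s <- mca_scores(7, n_horses = 4)
  z <- build_indicator(s)
  m <- fit_mca(z)
  # mass-weighted centering
  expect_lt(max(abs(colSums(m$row_coords * m$row_masses))), 1e-10)
  # CA transition: row principal = D_r^-1 P %*% col_standard
  p <- z / sum(z)
  col_std <- sweep(m$col_coords, 2, sqrt(m$eigenvalues), `/`)
  trans <- sweep(p %*% col_std, 1, m$row_masses, `/`)
  expect_equal(unname(trans), unname(m$row_coords), tolerance = 1e-8)
  # eigenvalues are non-increasing; explained fractions sum to 1
  expect_true(all(diff(m$eigenvalues) <= 1e-12))
  expect_equal(sum(m$explained_fraction), 1, tolerance = 1e-12)
})

test_that("explained fractions are invariant to duplicating rows", {
  s <- mca_scores(9, n_horses = 4)
  z <- build_indicator(s)
  m1 <- fit_mca(z)
  m2 <- fit_mca(rbind(z, z))
  expect_equal(m1$explained_fraction, m2$explained_fraction,
               tolerance = 1e-10)
})

test_that("two perfectly associated binary items load one dimension", {
  n <- 40
  a <- rep(c(0L, 1L), each = n / 2)
  s <- dplyr::bind_rows(
    tibble::tibble(horse = sprintf("h%d", 1:n), occasion = "b0",
                   phase = "pre", observer = "o1", scale = "HGS",
                   item = "orb", score = a),
    tibble::tibble(horse = sprintf("h%d", 1:n), occasion = "b0",
                   phase = "pre", observer = "o1", scale = "HGS",
                   item = "ears", score = a)
  )
  m <- fit_mca(build_indicator(s))
  # all non-degenerate inertia sits on the single association axis
  expect_equal(m$explained_fraction[1], 1, tolerance = 1e-10)
  expect_equal(m$eigenvalues[1], 1, tolerance = 1e-10)
  expect_equal(length(m$eigenvalues), 1)
})

test_that("dimension selection applies the explained-fraction threshold", {
  m <- structure(list(explained_fraction = c(0.10, 0.05, 0.009),
                      eigenvalues = c(1, 0.5, 0.09)), class = "mca_fit")
  expect_equal(select_dims(m), 1:2)
  m$explained_fraction <- c(0.5, 0.3, 0.2)
  expect_equal(select_dims(m), 1:3)
})

test_that("degenerate indicator input errors", {
  expect_error(fit_mca(matrix(1, 1, 3)), "degenerate")
  expect_error(fit_mca(matrix(0, 4, 3)), "empty")
})

test_that("a planted dimension effect is retained and significant", {
  s <- mca_scores(11, n_horses = 8, n_post = 4)
  z <- build_indicator(s)
  m <- fit_mca(z)
  keys <- attr(z, "keys")
  set.seed(99)
  y <- 30 * m$row_coords[, 1] + rnorm(nrow(z), sd = 10)
  reg <- regress_dims(m$row_coords, y, keys$horse, keys$observer,
                      dims = 1:8)
  expect_true(1 %in% reg$included_dims)
  expect_true(1 %in% reg$significant_dims)
  expect_equal(reg$table$beta[reg$table$dim == 1], 30, tolerance = 0.2)
  # AIC trace decreases along accepted eliminations
  expect_true(all(diff(reg$aic_trace$aic) < 0))
})

test_that("interpretation follows the sign rule and is flip-invariant", {
  s <- mca_scores(13, n_horses = 6)
  z <- build_indicator(s)
  m <- fit_mca(z)
  keys <- attr(z, "keys")
  set.seed(5)
  y <- 25 * m$row_coords[, 2] + rnorm(nrow(z), sd = 8)
  reg <- regress_dims(m$row_coords, y, keys$horse, keys$observer, dims = 1:4)
  expect_true(2 %in% reg$included_dims)
  out <- interpret_dim(m, reg, 2, contrib_threshold = 0.01)
  beta2 <- reg$table$beta[reg$table$dim == 2]
  expect_equal(out$association,
               ifelse(beta2 * out$coord > 0, "positive", "negative"))
  # flipping the dimension flips coordinates and beta, not associations
  m_f <- m
  m_f$col_coords[, 2] <- -m_f$col_coords[, 2]
  m_f$row_coords[, 2] <- -m_f$row_coords[, 2]
  reg_f <- regress_dims(m_f$row_coords, y, keys$horse, keys$observer,
                        dims = 1:4)
  out_f <- interpret_dim(m_f, reg_f, 2, contrib_threshold = 0.01)
  both <- dplyr::inner_join(out, out_f, by = "category")
  expect_equal(both$association.x, both$association.y)
  expect_error(interpret_dim(m, reg, 99), "not in the final model")
})
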