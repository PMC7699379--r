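# independent oracles used to cross-check the implementation

# Kendall's W from the definition, with mid-ranks computed by counting
# (no rank()), rank-sum mean taken as m(n+1)/2
oracle_kendalls_w <- function(x) {
  n <- nrow(x)
  m <- ncol(x)
  ranks <- sapply(seq_len(m), function(j) {
    sapply(seq_len(n), function(i) {
      1 + sum(x[, j] < x[i, j]) + (sum(x[, j] == x[i, j]) - 1) / 2
    })
  })
  rs <- rowSums(ranks)
  s <- sum((rs - m * (n + 1) / 2)^2)
  tj <- sapply(seq_len(m), function(j) {
    tt <- as.numeric(table(x[, j]))
    sum(tt^3 - tt)
  })
  12 * s / (m^2 * (n^3 - n) - m * sum(tj))
}

# minima difference of the noiseless continuous gait signal by dense
# numerical minimization over the two stance halves (right half centred
# on t = 0, left half on t = T/2, per the roll convention)
oracle_min_diff <- function(amp, asym, f) {
  z <- function(t) -amp * cos(4 * pi * f * t) + (asym / 2) * cos(2 * pi * f * t)
  T <- 1 / f
  right <- stats::optimize(z, c(-T / 4, T / 4), tol = 1e-12)$objective
  left <- stats::optimize(z, c(T / 4, 3 * T / 4), tol = 1e-12)$objective
  right - left
}

# principal inertias of the Burt-matrix correspondence analysis: the
# eigenvalues of the standardized Burt residual matrix equal the
# indicator-route principal inertias
oracle_burt_eigenvalues <- function(z) {
  b <- crossprod(z)
  pb <- b / sum(b)
  cm <- colSums(pb)
  s <- (pb - tcrossprod(cm)) / sqrt(tcrossprod(cm))
  ev <- eigen(s, symmetric = TRUE)$values
  ev[ev > 1e-9]
}

# a minimal valid long score table: 2 horses x 2 occasions x 1 phase x
# 2 observers over a chosen set of items
tiny_scores <- function(seed = 1, scales = pain_scales()) {
  set.seed(seed)
  grid <- expand.grid(horse = c("h1", "h2"), occasion = c("b0", "p1"),
                      phase = "pre", observer = c("o1", "o2"),
                      stringsAsFactors = FALSE)
  out <- merge(grid, scales[, c("scale", "item", "max_score")])
  out$score <- vapply(out$max_score,
                      function(m) sample(0:m, 1), integer(1))
  tibble::as_tibble(out[, c("horse", "occasion", "phase", "observer",
                            "scale", "item", "score")])
}

# random ordinal rating table: n assessments x m observers with scores
# in 0..max_score (ties guaranteed by the narrow range)
random_rating_table <- function(n = 6, m = 3, max_score = 3) {
  matrix(sample(0:max_score, n * m, replace = TRUE), n, m)
}
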