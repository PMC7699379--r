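# internal helpers shared across modules

# evaluate `code` under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# derive a child seed from a base seed and an index, kept inside 32-bit range
child_seed <- function(seed, index) {
  (as.double(seed) * 1009 + as.double(index) * 9973) %% 2147483647
}

# canonical occasion ordering: baseline "b0" first, then post occasions by
# numeric suffix ("p1", "p2", ...); anything else sorts after, alphabetically
occasion_levels <- function(x) {
  u <- unique(as.character(x))
  base <- u[u == "b0"]
  post <- u[grepl("^p[0-9]+$", u)]
  post <- post[order(as.integer(sub("^p", "", post)))]
  other <- sort(setdiff(u, c(base, post)))
  c(base, post, other)
}

# lower-case design-matrix prefix for a scale id
scale_prefix <- function(scale) {
  pref <- c(HGS = "hgs", EQUUS_FAP = "fap", EPS = "eps", CPS = "cps")
  out <- unname(pref[scale])
  out[is.na(out)] <- tolower(scale[is.na(out)])
  out
}
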