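#' Pain-scale item registry
#'
#' Loads the machine-readable definitions of the four equine pain scales
#' used throughout the package: the Horse Grimace Scale (HGS, 6 facial
#' items scored 0--2), the Equine Utrecht University Scale of Facial
#' Assessment of Pain (EQUUS-FAP, 9 items, 0--2), the Equine Pain Scale
#' (EPS, 9 behavioral items, 0--4) and the Composite Pain Scale (CPS,
#' 9 behavioral items plus 4 objectively measured physiological items,
#' 0--3).  Item abbreviations are the short identifiers used in design
#' matrices and coefficient names (e.g. `hgs_orb1` is score 1 on orbital
#' tightening).
#'
#' @param path Path to a scale-definition JSON file.  Defaults to the
#'   registry shipped with the package.
#' @return A tibble with one row per scale item and columns `scale`,
#'   `item`, `label`, `min_score`, `max_score`, `physiological`,
#'   `behavioral`.  Row order is scale then registry order.
#' @examples
#' pain_scales()
#' @export
pain_scales <- function(path = system.file("extdata", "scales.json",
                                           package = "equiasym")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("scale definition resource not found", call. = FALSE)
  }
  raw <- jsonlite::fromJSON(path)
  required <- c("scale", "item", "label", "min_score", "max_score",
                "physiological")
  if (!is.data.frame(raw) || !all(required %in% names(raw))) {
    stop("malformed scale definition resource", call. = FALSE)
  }
  out <- tibble::as_tibble(raw)
  out$min_score <- as.integer(out$min_score)
  out$max_score <- as.integer(out$max_score)
  out$behavioral <- !out$physiological
  dup <- duplicated(out[, c("scale", "item")])
  if (any(dup)) stop("duplicate (scale, item) pair in registry", call. = FALSE)
  out
}

#' Validate a long-format score table against the scale registry
#'
#' Checks every row of a long score table for unknown scales or items,
#' non-integer scores, and scores outside the item's range.  Problems are
#' returned as rows rather than raised, so a whole table can be audited
#' in one pass.
#'
#' @param scores A data frame with at least `scale`, `item`, `score`
#'   columns (the long format also carries `horse`, `occasion`, `phase`,
#'   `observer`).
#' @param scales Scale registry, as returned by [pain_scales()].
#' @return A tibble of violations with columns `row`, `scale`, `item`,
#'   `score`, `problem`; zero rows when the table is clean.
#' @examples
#' tab <- tibble::tibble(scale = "HGS", item = "orb", score = 3)
#' validate_scores(tab)
#' @export
validate_scores <- function(scores, scales = pain_scales()) {
  stopifnot(is.data.frame(scores))
  need <- c("scale", "item", "score")
  missing_cols <- setdiff(need, names(scores))
  if (length(missing_cols) > 0) {
    stop("score table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  joined <- dplyr::left_join(
    dplyr::mutate(scores[, need], row = dplyr::row_number()),
    scales[, c("scale", "item", "min_score", "max_score")],
    by = c("scale", "item")
  )
  unknown <- is.na(joined$min_score)
  non_int <- !unknown &
    (!is.numeric(joined$score) | is.na(joined$score) |
       joined$score != round(joined$score))
  out_of_range <- !unknown & !non_int &
    (joined$score < joined$min_score | joined$score > joined$max_score)
  problem <- dplyr::case_when(
    unknown ~ "unknown item",
    non_int ~ "non-integer score",
    out_of_range ~ "score out of range",
    .default = NA_character_
  )
  bad <- !is.na(problem)
  tibble::tibble(
    row = joined$row[bad],
    scale = joined$scale[bad],
    item = joined$item[bad],
    score = joined$score[bad],
    problem = problem[bad]
  )
}

#' Published inter-observer agreement coefficients
#'
#' Reference Kendall's W coefficients for the 33 behavioral items of the
#' four scales, as reported for three observers assessing LPS-induced
#' orthopedic pain.  Shipped so that the agreement banding rule can be
#' exercised against a realistic coefficient set.
#'
#' @return A tibble with columns `scale`, `item`, `w`, `p_printed`.
#' @export
reference_w <- function() {
  path <- system.file("extdata", "reference_w.csv", package = "equiasym")
  readr::read_csv(path, col_types = readr::cols(
    scale = readr::col_character(),
    item = readr::col_character(),
    w = readr::col_double(),
    p_printed = readr::col_character()
  ))
}
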