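# Fingerprint comparison: city-block distance, median-calibrated
# similarity scores, nearest-neighbor search, reference similarity
# fingerprints, and retrieval statistics.

fp_matrix <- function(db) {
  if (!all(bit_names() %in% names(db))) {
    abort_contract("fingerprint table lacks B1..B136 columns")
  }
  m <- as.matrix(db[, bit_names()])
  rownames(m) <- db$entry_id
  m
}

#' City-block distance between two fingerprints
#'
#' The sum of absolute bit differences — the similarity measure of the
#' fingerprint space. Accepts bare numeric vectors or one-row
#' fingerprint tibbles.
#'
#' @param a,b fingerprints of equal length.
#' @return a non-negative number.
#' @export
#' @examples
#' cbd(c(5, 0, 1), c(0, 3, 1))
cbd <- function(a, b) {
  a <- as_bits(a)
  b <- as_bits(b)
  if (length(a) != length(b)) abort_contract("fingerprint lengths differ")
  sum(abs(a - b))
}

as_bits <- function(x) {
  if (is.data.frame(x)) {
    if (nrow(x) != 1) abort_contract("expected a single fingerprint row")
    as.numeric(unlist(x[, intersect(bit_names(), names(x)), drop = FALSE]))
  } else {
    as.numeric(x)
  }
}

# CBDs from one query fingerprint to every row of a database
cbd_to_all <- function(db, query) {
  m <- fp_matrix(db)
  q <- as_bits(query)
  if (length(q) != ncol(m)) abort_contract("fingerprint lengths differ")
  as.vector(rowSums(abs(sweep(m, 2, q))))
}

#' Calibrate the similarity score on a fingerprint database
#'
#' Samples random distinct unordered pairs of entries (uniformly, with
#' replacement across pairs) and takes the median of their city-block
#' distances. That median X anchors the similarity transform
#' `S = X / (CBD + X)`, so a typical random pair scores 0.5. At
#' full-database scale one million pairs are used; for small databases
#' the default shrinks to `20 * N^2`, enough to estimate a median.
#'
#' @param db a fingerprint tibble (>= 2 entries).
#' @param n_pairs number of sampled pairs.
#' @param seed integer seed making the draw reproducible.
#' @return a list of class `sim_calibration`: `X`, `n_pairs`, `seed`.
#' @export
calibrate_similarity <- function(db, n_pairs = NULL, seed = 1L) {
  n <- nrow(db)
  if (n < 2) abort_contract("calibration needs at least 2 entries")
  if (is.null(n_pairs)) n_pairs <- min(1e6, 20 * n^2)
  if (n_pairs < 1) abort_contract("n_pairs must be positive")
  m <- fp_matrix(db)
  cbds <- withr::with_seed(seed, {
    i <- sample.int(n, n_pairs, replace = TRUE)
    j <- sample.int(n, n_pairs, replace = TRUE)
    while (any(i == j)) {
      eq <- which(i == j)
      j[eq] <- sample.int(n, length(eq), replace = TRUE)
    }
    rowSums(abs(m[i, , drop = FALSE] - m[j, , drop = FALSE]))
  })
  structure(
    list(X = stats::median(cbds), n_pairs = as.integer(n_pairs), seed = as.integer(seed)),
    class = "sim_calibration"
  )
}

#' @export
print.sim_calibration <- function(x, ...) {
  cat(sprintf("similarity calibration: X = %g (median CBD of %d sampled pairs, seed %d)\n",
              x$X, x$n_pairs, x$seed))
  invisible(x)
}

#' Similarity score from a city-block distance
#'
#' `S = X / (CBD + X)` with X the calibrated median random-pair
#' distance: identical fingerprints score 1, a median-distant pair 0.5,
#' and the score decays toward 0 with distance.
#'
#' @param cbd_value non-negative CBD value(s).
#' @param calibration a `sim_calibration`, or a bare positive number X.
#' @return scores in (0, 1].
#' @export
similarity_score <- function(cbd_value, calibration) {
  x <- if (inherits(calibration, "sim_calibration")) calibration$X else as.numeric(calibration)
  if (!is.finite(x) || x <= 0) abort_contract("calibration X must be positive")
  if (any(cbd_value < 0)) abort_contract("CBD must be non-negative")
  x / (cbd_value + x)
}

#' Rank database entries by distance to a query fingerprint
#'
#' Brute-force city-block nearest-neighbor search over the fingerprint
#' table, ascending by CBD with ties broken lexicographically by entry
#' id so rankings are deterministic.
#'
#' @param db a fingerprint tibble.
#' @param query a fingerprint (one-row tibble or numeric vector) or an
#'   `entry_id` present in `db`.
#' @param k number of neighbors (capped at the database size).
#' @param calibration optional `sim_calibration`; when supplied a
#'   similarity-score column is included.
#' @return a tibble `rank`, `entry_id`, `cbd` (and `s3dp`).
#' @export
nearest_neighbors <- function(db, query, k = 10, calibration = NULL) {
  if (nrow(db) == 0) abort_contract("empty database")
  if (k < 1) abort_contract("k must be >= 1")
  if (is.character(query) && length(query) == 1) {
    hit <- which(db$entry_id == query)
    if (length(hit) == 0) abort_notfound(sprintf("entry '%s' not in database", query))
    query <- db[hit[1], ]
  }
  d <- cbd_to_all(db, query)
  ord <- order(d, db$entry_id)
  ord <- ord[seq_len(min(k, length(ord)))]
  out <- tibble(rank = seq_along(ord), entry_id = db$entry_id[ord], cbd = d[ord])
  if (!is.null(calibration)) out$s3dp <- similarity_score(out$cbd, calibration)
  out
}

#' Reference-panel similarity fingerprints
#'
#' Reduces each entry's 136-bit fingerprint to a vector of similarity
#' scores against a fixed, seed-reproducible random panel of reference
#' entries (200 at full-database scale). These similarity fingerprints
#' are the input of the PCA shape-space map, which is much better
#' behaved on them than on the raw bit vectors.
#'
#' @param db a fingerprint tibble with at least `n_refs` entries.
#' @param n_refs panel size (default `min(200, floor(nrow(db) / 2))` so
#'   small databases work; 200 is used whenever the database permits).
#' @param seed integer seed selecting the panel.
#' @param calibration a `sim_calibration`; computed from `db` (with the
#'   same seed) when omitted.
#' @return a tibble with `entry_id` and one score column per reference
#'   (named `S_<reference id>`); the panel ids are in the
#'   `"reference_ids"` attribute and the calibration in `"calibration"`.
#' @export
similarity_fingerprints <- function(db, n_refs = NULL, seed = 1L, calibration = NULL) {
  n <- nrow(db)
  if (is.null(n_refs)) n_refs <- min(200L, floor(n / 2))
  if (n_refs < 1 || n < n_refs) abort_contract("database smaller than the reference panel")
  if (is.null(calibration)) calibration <- calibrate_similarity(db, seed = seed)
  refs <- withr::with_seed(seed, sort(sample.int(n, n_refs)))
  ref_ids <- db$entry_id[refs]
  m <- fp_matrix(db)
  rm <- m[refs, , drop = FALSE]
  # n x n_refs CBD matrix via |a-b| = a+b - 2*min is not available; loop refs
  scores <- vapply(seq_len(n_refs), function(j) {
    similarity_score(rowSums(abs(sweep(m, 2, rm[j, ]))), calibration)
  }, numeric(n))
  if (n == 1) scores <- matrix(scores, nrow = 1)
  out <- tibble(entry_id = db$entry_id)
  colnames(scores) <- paste0("S_", ref_ids)
  out <- dplyr::bind_cols(out, as_tibble(scores))
  attr(out, "reference_ids") <- ref_ids
  attr(out, "calibration") <- calibration
  out
}

#' ROC area and enrichment factor of a ranked retrieval
#'
#' Given ranking-ordered active/inactive labels (best rank first),
#' computes the area under the ROC curve (trapezoidal, in percent) and
#' the enrichment factor at fraction `f`: the proportion of actives
#' among the top `ceiling(f * N)` entries divided by `f` (a perfect
#' early ranking reaches `1 / f`).
#'
#' @param ranked_labels logical vector, `TRUE` for actives, ordered by
#'   the ranking under evaluation.
#' @param f top-list fraction for the enrichment factor (default 0.001,
#'   i.e. EF at 0.1 % coverage).
#' @return a one-row tibble: `auc` (percent), `ef`, `f`, `n_actives`,
#'   `n`.
#' @export
#' @examples
#' roc_enrichment(c(TRUE, TRUE, FALSE, FALSE), f = 0.5)
roc_enrichment <- function(ranked_labels, f = 0.001) {
  lab <- as.logical(ranked_labels)
  n_act <- sum(lab)
  n_in <- sum(!lab)
  if (n_act == 0 || n_in == 0) abort_contract("need at least one active and one inactive")
  if (f <= 0 || f > 1) abort_contract("f must be in (0, 1]")
  n <- length(lab)
  # trapezoidal AUC == Mann-Whitney statistic for a strict ranking
  rank_act <- which(lab)
  u <- sum(n - rank_act - (n_act - seq_len(n_act)))
  auc <- 100 * u / (n_act * n_in)
  top <- seq_len(min(n, ceiling(f * n)))
  ef <- (sum(lab[top]) / length(top)) / f
  tibble(auc = auc, ef = ef, f = f, n_actives = n_act, n = n)
}
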