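# Virtual screening: Mixture Generator Beta (unlabeled candidate universe),
# batch classification, compound filtering, score binning, CSV export and
# mixture-space combinatorics.

#' Generate an unlabeled candidate-mixture universe
#'
#' Mixture Generator Beta: like the negative-mixture generator (random
#' component count, random distinct components, random coefficients) but
#' assigns no label and performs no database-collision rejection.  For large
#' `n` the universe is kept as index/coefficient matrices and only rendered
#' to encoded strings on demand.
#'
#' @param n number of mixtures.
#' @param library compound library `data.frame` (`name`, `smiles`).
#' @param seed integer seed.
#' @param k_range component-count range (default 3:5).
#' @param coef_range coefficient range (default 1:10).
#' @return object of class `mixture_universe`.
#' @export
generate_universe <- function(n, library, seed = 1L, k_range = 3:5,
                              coef_range = 1:10) {
  if (n < 0L) stop_ns("n must be >= 0")
  if (nrow(library) < max(k_range))
    stop_ns("library has %d compounds; need at least %d", nrow(library), max(k_range))
  kmax <- max(k_range)
  with_seed(seed, {
    comp <- matrix(NA_integer_, n, kmax)
    coef <- matrix(NA_integer_, n, kmax)
    k <- if (n > 0L) sample_vec(k_range, n, replace = TRUE) else integer(0)
    nlib <- nrow(library)
    for (i in seq_len(n)) {
      ki <- k[i]
      comp[i, seq_len(ki)] <- sample.int(nlib, ki)
      coef[i, seq_len(ki)] <- sample_vec(coef_range, ki, replace = TRUE)
    }
    structure(list(comp = comp, coef = coef, k = k, library = library,
                   size = as.integer(n), seed = as.integer(seed),
                   k_range = k_range, coef_range = coef_range),
              class = "mixture_universe")
  })
}

#' @export
print.mixture_universe <- function(x, ...) {
  cat(sprintf("<mixture_universe> %d unlabeled mixtures over %d compounds (k in %d..%d)\n",
              x$size, nrow(x$library), min(x$k_range), max(x$k_range)))
  invisible(x)
}

#' Render a universe to encoded mixture strings
#'
#' @param universe a [generate_universe()] result.
#' @return character vector of [encode_mixture()] strings, one per mixture.
#' @export
encode_universe <- function(universe) {
  stopifnot(inherits(universe, "mixture_universe"))
  smiles <- universe$library$smiles
  vapply(seq_len(universe$size), function(i) {
    ki <- universe$k[i]
    s <- smiles[universe$comp[i, seq_len(ki)]]
    cf <- universe$coef[i, seq_len(ki)]
    ord <- order_c(s, cf)
    paste0("[R", cf[ord], "]", s[ord], collapse = ".")
  }, character(1L))
}

#' @rdname encode_universe
#' @param path destination text file, one encoded mixture per line.
#' @export
write_universe <- function(universe, path) {
  writeLines(encode_universe(universe), path, useBytes = TRUE)
  invisible(path)
}

#' Fraction of universe mixtures containing a compound
#'
#' With k components drawn uniformly without replacement from N compounds
#' the inclusion probability of any single compound is E[k]/N (by symmetry);
#' for k uniform on \{3,4,5\} over a 198-compound library this is
#' 4/198, about 2%.
#'
#' @param universe a [generate_universe()] result.
#' @param smiles compound SMILES to look for.
#' @return proportion of mixtures containing the compound.
#' @export
universe_contains_fraction <- function(universe, smiles) {
  idx <- match(smiles, universe$library$smiles)
  if (is.na(idx)) return(0)
  mean(rowSums(universe$comp == idx, na.rm = TRUE) > 0L)
}

#' Score a candidate universe with a classifier
#'
#' Streams over batches so memory stays bounded by the batch size; output
#' order equals input order and is independent of the batch size.
#'
#' @param classifier a `stability_classifier`.
#' @param universe a `mixture_universe`, a character vector of encoded
#'   mixtures, or a path to a universe text file.
#' @param batch_size scoring batch size.
#' @return `data.frame` with columns `encoded`, `score`, `label`, one row
#'   per input mixture.
#' @export
screen_universe <- function(classifier, universe, batch_size = 64L) {
  encoded <- if (inherits(universe, "mixture_universe")) {
    encode_universe(universe)
  } else if (is.character(universe) && length(universe) == 1L &&
             file.exists(universe)) {
    readLines(universe, encoding = "UTF-8")
  } else if (is.character(universe)) {
    universe
  } else stop_ns("cannot screen object of class %s", class(universe)[1L])
  for (i in seq_along(encoded)) {
    if (!grepl("^\\[R", encoded[[i]]))
      stop_ns("universe line %d is not an encoded mixture: %s", i,
              sQuote(encoded[[i]]))
  }
  predict_scores(classifier, encoded, batch_size = batch_size)
}

# component SMILES of each encoded string, as a list
encoded_components <- function(encoded) {
  lapply(strsplit(encoded, ".", fixed = TRUE), function(parts)
    sub("^\\[R(10|[1-9])\\]", "", parts))
}

#' Filter scored mixtures by a contained compound
#'
#' Keeps exactly the records whose component multiset contains the query
#' compound (matched on canonical SMILES), sorted by descending score with
#' ties broken by the encoded string (byte order).
#'
#' @param scored `data.frame` from [screen_universe()] / [predict_scores()].
#' @param query compound SMILES to require.
#' @param canonicalizer canonicalizer applied to the query before matching.
#' @return filtered and sorted `data.frame`.
#' @export
filter_by_compound <- function(scored, query,
                               canonicalizer = identity_canonicalizer(quiet = TRUE)) {
  query <- canonicalize_smiles(query, canonicalizer)
  comp <- encoded_components(scored$encoded)
  keep <- vapply(comp, function(s) query %in% s, logical(1L))
  out <- scored[keep, , drop = FALSE]
  out[order(-out$score, rank_c(out$encoded)), , drop = FALSE]
}

# byte-order rank helper (ties in score are broken lexicographically)
rank_c <- function(x) match(x, sort_c(unique(x)))

SCORE_BIN_BREAKS <- seq(50, 100, by = 5)
SCORE_BIN_LABELS <- paste0(utils::head(SCORE_BIN_BREAKS, -1L) + 0.1, "-",
                           SCORE_BIN_BREAKS[-1L])

#' Bin stability scores into 5-point histogram bins
#'
#' Only records with score strictly above 50% are binned; the bins are
#' left-open five-percentage-point intervals labeled "50.1-55" through
#' "95.1-100" (a score of exactly 85% falls in "80.1-85").
#'
#' @param scored `data.frame` with a `score` column (probabilities in
#'   (0, 1)).
#' @return object of class `score_histogram`: `data.frame` with columns
#'   `bin` and `count`, plus attribute `total` (number of records binned).
#' @export
bin_scores <- function(scored) {
  pct <- scored$score * 100
  pct <- pct[pct > 50]
  cuts <- cut(pct, breaks = SCORE_BIN_BREAKS, labels = SCORE_BIN_LABELS,
              right = TRUE)
  tab <- table(cuts)
  out <- data.frame(bin = SCORE_BIN_LABELS,
                    count = as.integer(tab[SCORE_BIN_LABELS]),
                    stringsAsFactors = FALSE)
  out$count[is.na(out$count)] <- 0L
  structure(out, total = length(pct), class = c("score_histogram", "data.frame"))
}

#' Export scored mixtures to CSV
#'
#' Columns: `components` (";"-joined SMILES), `ratios` (":"-joined
#' coefficients, molar-ratio style), `encoded`, `score` (4 decimals) and
#' `label`.  Row order is preserved from the input (use
#' [filter_by_compound()] first for the ranked ordering); re-export of the
#' same input is byte-identical.
#'
#' @param scored `data.frame` with columns `encoded`, `score`, `label`.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
export_results_csv <- function(scored, path) {
  comp <- encoded_components(scored$encoded)
  ratios <- lapply(strsplit(scored$encoded, ".", fixed = TRUE), function(parts)
    sub("^\\[R(10|[1-9])\\].*$", "\\1", parts))
  rows <- vapply(seq_len(nrow(scored)), function(i)
    paste(paste(comp[[i]], collapse = ";"),
          paste(ratios[[i]], collapse = ":"),
          scored$encoded[[i]],
          sprintf("%.4f", scored$score[[i]]),
          scored$label[[i]], sep = ","),
    character(1L))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("components,ratios,encoded,score,label", rows), con, useBytes = TRUE)
  invisible(path)
}

#' Count ternary combinations of a compound pool
#'
#' Exact binomial coefficient `choose(pool_size, 3)` computed in integer
#' arithmetic; for a 618-entry pool this is 39,147,416 ("approximately 40
#' million" possible ternary mixtures).
#'
#' @param pool_size number of choosable entries; at least 3.
#' @return exact count as a numeric (integer-valued; exactness is guaranteed
#'   up to pool sizes of about 200,000, far beyond any compound library, and
#'   enforced with an error beyond that).
#' @examples
#' count_ternary_combinations(618)  # 39147416
#' @export
count_ternary_combinations <- function(pool_size) {
  pool_size <- as.numeric(pool_size)
  if (length(pool_size) != 1L || is.na(pool_size) || pool_size != floor(pool_size))
    stop_ns("pool_size must be a single integer")
  if (pool_size < 3) stop_ns("pool_size must be at least 3 (got %g)", pool_size)
  num <- pool_size * (pool_size - 1) * (pool_size - 2)
  if (num >= 2^53)
    stop_ns("pool_size %g exceeds the exact integer range of this implementation",
            pool_size)
  num / 6
}
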