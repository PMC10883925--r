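# Mixture Generator Alpha: random negative mixtures for rebalancing the
# labeled training set.  Rationale: the chance that a random combination of
# compounds at random stoichiometric coefficients forms a stable eutectic
# solvent is very low, so random mixtures can be labeled unstable (0) with a
# small, quantifiable error.

#' Augmentation plan
#'
#' Records the generator parameters and provenance for a batch of random
#' negatives.
#'
#' @param n_negatives number of negatives to generate (the reference study
#'   used levels 1, 5, 10, 25, 50, 100, 500; any non-negative integer works).
#' @param library compound library `data.frame` (`name`, `smiles`).
#' @param component_range inclusive range of component counts (default 3:5).
#' @param coefficient_range inclusive coefficient range (default 1:10).
#' @param seed integer seed.
#' @return object of class `augmentation_plan`.
#' @export
augmentation_plan <- function(n_negatives, library, component_range = 3:5,
                              coefficient_range = 1:10, seed = 1L) {
  if (n_negatives < 0L) stop_ns("n_negatives must be >= 0")
  if (nrow(library) < 5L)
    stop_ns("library has %d compounds; at least 5 required", nrow(library))
  structure(list(n_negatives = as.integer(n_negatives), library = library,
                 component_range = component_range,
                 coefficient_range = coefficient_range,
                 library_size = nrow(library), seed = as.integer(seed)),
            class = "augmentation_plan")
}

#' Generate random negative mixtures
#'
#' Each mixture draws `k` uniformly from the component range, `k` distinct
#' components without replacement from the library, and coefficients
#' uniformly from the coefficient range; all are labeled 0 (unstable).  Any
#' draw whose (SMILES, coefficient) multiset equals a known-database entry or
#' an earlier draw is rejected and redrawn; the rejection loop is capped.
#'
#' @param plan an [augmentation_plan()] (or an integer, taken as
#'   `n_negatives` with the remaining arguments).
#' @param known_db list of [mixture()] objects the negatives must not
#'   collide with (e.g. the labeled database).
#' @param max_attempts rejection cap.
#' @inheritParams augmentation_plan
#' @return list of [mixture()] objects, all labeled 0.
#' @export
generate_negative_mixtures <- function(plan, known_db = list(), library = NULL,
                                       component_range = 3:5,
                                       coefficient_range = 1:10, seed = 1L,
                                       max_attempts = NULL) {
  if (!inherits(plan, "augmentation_plan"))
    plan <- augmentation_plan(plan, library, component_range, coefficient_range, seed)
  n <- plan$n_negatives
  if (n == 0L) return(list())
  max_attempts <- max_attempts %||% (100L * n + 1000L)
  known <- new.env(hash = TRUE, parent = emptyenv())
  for (key in mixture_keys(known_db)) known[[key]] <- TRUE
  lib <- plan$library
  with_seed(plan$seed, {
    out <- vector("list", n)
    got <- 0L; attempts <- 0L
    while (got < n) {
      if (attempts >= max_attempts)
        stop_ns(paste0("negative-mixture generator exhausted after %d attempts ",
                       "(%d/%d generated); the requested slice of mixture space ",
                       "appears to be (nearly) fully enumerated"),
                attempts, got, n)
      attempts <- attempts + 1L
      k <- sample_vec(plan$component_range, 1L)
      idx <- sample.int(nrow(lib), k)
      cf <- sample_vec(plan$coefficient_range, k, replace = TRUE)
      m <- mixture(lib$smiles[idx], cf, label = 0L, names = lib$name[idx])
      key <- mixture_key(m)
      if (!is.null(known[[key]])) next
      known[[key]] <- TRUE
      got <- got + 1L
      out[[got]] <- m
    }
    out
  })
}

#' Augment a training set with generated negatives
#'
#' Concatenates and shuffles (seeded).  The test set is untouched by
#' contract: augmentation only ever applies to training data.
#'
#' @param train list of labeled [mixture()] objects.
#' @param negatives list of mixtures, all labeled 0 (enforced).
#' @param seed shuffle seed.
#' @return shuffled concatenation.
#' @export
augment_training_set <- function(train, negatives, seed = 1L) {
  if (length(negatives) > 0L) {
    labs <- mixture_labels(negatives)
    if (anyNA(labs) || any(labs != 0L))
      stop_ns("all augmentation negatives must carry label 0")
  }
  out <- c(train, negatives)
  with_seed(seed, out[sample.int(length(out))])
}
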