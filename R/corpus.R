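# Reaction-corpus preparation and labeled-dataset splitting/deduplication.
#
# The pre-training corpus is plain text, one reaction per line, with the
# dot-joined reactant SMILES separated from the product SMILES by the
# non-SMILES character ">".  It is assembled from a source file (reactants)
# and a target file (products) whose lines pair up one-to-one.

#' Merge paired reactant/product line sets into a reaction corpus
#'
#' Line `i` of the output is `src[i] + ">" + tgt[i]`.
#'
#' @param src_lines character vector of reactant lines.
#' @param tgt_lines character vector of product lines, same length.
#' @return character vector of merged corpus lines.
#' @examples
#' merge_reaction_files("CCO.O", "CC=O")
#' @export
merge_reaction_files <- function(src_lines, tgt_lines) {
  if (length(src_lines) != length(tgt_lines))
    stop_ns("source and target line counts differ: %d vs %d",
            length(src_lines), length(tgt_lines))
  if (length(src_lines) == 0L) return(character(0))
  paste0(src_lines, ">", tgt_lines)
}

#' Merge a src-/tgt-file pair on disk
#'
#' Reads the `src-*.txt` / `tgt-*.txt` convention and writes the merged
#' one-reaction-per-line corpus.
#'
#' @param src_path,tgt_path input text files.
#' @param out_path merged corpus destination.
#' @return `out_path`, invisibly.
#' @export
merge_reaction_file_pair <- function(src_path, tgt_path, out_path) {
  merged <- merge_reaction_files(readLines(src_path, encoding = "UTF-8"),
                                 readLines(tgt_path, encoding = "UTF-8"))
  writeLines(merged, out_path, useBytes = TRUE)
  invisible(out_path)
}

split_reaction_line <- function(line) {
  parts <- strsplit(line, ">", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    stop_ns("corpus line does not contain exactly one '>': %s", sQuote(line))
  list(reactants = parts[[1]], products = parts[[2]])
}

#' Split a labeled mixture dataset into train and test
#'
#' Uniform random sample without replacement (unstratified, matching the
#' random 20% hold-out protocol); `|test| = round(test_fraction * N)`.
#' The same seed reproduces the identical split.
#'
#' @param db list of labeled [mixture()] objects.
#' @param test_fraction proportion in (0, 1); default 0.2.
#' @param seed integer seed.
#' @param stratify if `TRUE`, sample the test fraction within each label
#'   class (off by default; the reference protocol is unstratified).
#' @return an object of class `dataset_split` with elements `train`, `test`,
#'   `test_fraction`, `seed`.
#' @export
split_dataset <- function(db, test_fraction = 0.2, seed = 1L, stratify = FALSE) {
  if (!(test_fraction > 0 && test_fraction < 1))
    stop_ns("test_fraction must be strictly between 0 and 1 (got %g)", test_fraction)
  n <- length(db)
  idx_test <- with_seed(seed, {
    if (stratify) {
      labels <- mixture_labels(db)
      unlist(lapply(unique(labels), function(l) {
        pool <- which(labels == l)
        sample(pool, round(test_fraction * length(pool)))
      }), use.names = FALSE)
    } else {
      sample.int(n, round(test_fraction * n))
    }
  })
  idx_test <- sort(idx_test)
  structure(list(train = db[setdiff(seq_len(n), idx_test)],
                 test = db[idx_test],
                 test_fraction = test_fraction, seed = as.integer(seed)),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> train=%d test=%d (fraction %.2f, seed %d)\n",
              length(x$train), length(x$test), x$test_fraction, x$seed))
  invisible(x)
}

#' Remove train mixtures duplicated in the test set
#'
#' Two mixtures are duplicates when their multisets of
#' (canonical SMILES, coefficient) pairs are identical; component order is
#' irrelevant and ratios are never rescaled, so 1:1 and 2:2 of the same
#' compounds are distinct entries.
#'
#' @param train,test lists of [mixture()] objects.
#' @return list with `train` (filtered) and `report` (`data.frame` of
#'   removed indices and keys).
#' @export
dedup_across <- function(train, test) {
  tr_keys <- mixture_keys(train)
  te_keys <- unique(mixture_keys(test))
  drop <- tr_keys %in% te_keys
  list(train = train[!drop],
       report = data.frame(index = which(drop), key = tr_keys[drop],
                           stringsAsFactors = FALSE))
}
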