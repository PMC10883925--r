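# SMILES tokenization and vocabulary construction.

# Special tokens, in fixed id order.  ">" separates reactants from products
# in corpus lines; [R1]..[R10] are the stoichiometric-ratio tokens prefixed
# to each mixture component (deliberately absent from plain reaction SMILES).
PAD_TOKEN <- "[PAD]"
UNK_TOKEN <- "[UNK]"
CLS_TOKEN <- "[CLS]"
SEP_TOKEN <- "[SEP]"
MASK_TOKEN <- "[MASK]"
GT_TOKEN <- ">"
RATIO_TOKENS <- paste0("[R", 1:10, "]")

#' Special tokens of the mixture language
#'
#' @return character vector: PAD, UNK, CLS, SEP, MASK, the ">" reaction
#'   separator and the ratio tokens `[R1]`..`[R10]`, in vocabulary id order.
#' @export
special_tokens <- function() {
  c(PAD_TOKEN, UNK_TOKEN, CLS_TOKEN, SEP_TOKEN, MASK_TOKEN, GT_TOKEN, RATIO_TOKENS)
}

SMILES_TOKEN_RE <- "\\[[^]]*\\]|Cl|Br|%[0-9]{2}|."

#' Tokenize SMILES (and encoded-mixture) strings
#'
#' Regex-based atom-level tokenization: bracket atoms and the bracketed
#' special tokens (`[R2]`, `[MASK]`, ...) are single tokens, the two-letter
#' organic-subset atoms `Cl` and `Br` are single tokens, `%NN` ring closures
#' are single tokens, and every remaining character (ring digits, bonds,
#' branches, ".", ">") is its own token.  The tokenizer is lossless:
#' `paste(tokens, collapse = "")` reproduces the input exactly.  Unknown
#' characters simply become single-character tokens (mapped to UNK later by
#' the vocabulary).
#'
#' @param text character vector of strings to tokenize.
#' @return for a single string, a character vector of tokens; for a vector,
#'   a list of such vectors.
#' @examples
#' tokenize_smiles("CC(=O)O")
#' tokenize_smiles("[R2]CCO.[R1]O")
#' @export
tokenize_smiles <- function(text) {
  text <- as.character(text)
  out <- regmatches(text, gregexpr(SMILES_TOKEN_RE, text, perl = TRUE))
  if (length(text) == 1L) out[[1]] else out
}

#' Build a token vocabulary from a corpus
#'
#' Special tokens come first (fixed ids), then corpus tokens by descending
#' frequency, ties broken lexicographically (byte order), truncated to at
#' most `V` entries.  Tokens outside the vocabulary map to UNK at lookup.
#'
#' @param corpus character vector of corpus lines (one record per line).
#' @param V vocabulary size cap; must exceed the number of special tokens.
#' @return an object of class `smiles_vocab`.
#' @export
build_vocabulary <- function(corpus, V = 30000L) {
  specials <- special_tokens()
  if (length(corpus) == 0L) stop_ns("cannot build a vocabulary from an empty corpus")
  if (V < length(specials) + 1L)
    stop_ns("vocabulary cap V = %d is too small for %d special tokens", V, length(specials))
  toks <- unlist(tokenize_smiles(corpus), use.names = FALSE)
  toks <- toks[!toks %in% specials]
  freq <- table(toks)
  tok_names <- names(freq)
  ord <- order_c(-as.integer(freq), tok_names)
  regular <- tok_names[ord]
  n_keep <- min(length(regular), V - length(specials))
  tokens <- c(specials, regular[seq_len(n_keep)])
  ids <- seq_along(tokens) - 1L
  names(ids) <- tokens
  structure(list(tokens = tokens, token_to_id = ids, V = as.integer(V)),
            class = "smiles_vocab")
}

#' @export
print.smiles_vocab <- function(x, ...) {
  cat(sprintf("<smiles_vocab> %d tokens (%d special), cap %d\n",
              length(x$tokens), length(special_tokens()), x$V))
  invisible(x)
}

vocab_size <- function(vocab) length(vocab$tokens)

# token -> 0-based id, unknown tokens -> id of [UNK]
vocab_ids <- function(vocab, tokens) {
  ids <- unname(vocab$token_to_id[tokens])
  ids[is.na(ids)] <- unname(vocab$token_to_id[UNK_TOKEN])
  as.integer(ids)
}

vocab_tokens_of <- function(vocab, ids) vocab$tokens[ids + 1L]

write_vocabulary <- function(vocab, path) {
  writeLines(vocab$tokens, path, useBytes = TRUE)
  invisible(path)
}

read_vocabulary <- function(path, V = NULL) {
  tokens <- readLines(path, encoding = "UTF-8")
  ids <- seq_along(tokens) - 1L
  names(ids) <- tokens
  structure(list(tokens = tokens, token_to_id = ids,
                 V = as.integer(V %||% length(tokens))),
            class = "smiles_vocab")
}
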