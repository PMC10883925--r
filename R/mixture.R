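# Mixture specifications and their single-line string encoding.
#
# A mixture is a multiset of (compound SMILES, integer stoichiometric
# coefficient) pairs, optionally carrying a binary stability label
# (1 = stable for more than a week at room temperature, 0 = not).  The
# classifier consumes mixtures as single-line strings in which every
# component is prefixed by its ratio token: "[R2]CCO.[R1]O" is two parts
# ethanol to one part water.

#' Construct a mixture specification
#'
#' @param smiles character vector of component SMILES (canonical under the
#'   canonicalizer in use).
#' @param coef integer stoichiometric coefficients, one per component.
#' @param label optional stability label, `1` (stable), `0` (unstable) or
#'   `NA` (unlabeled).
#' @param names optional free-text component names.
#' @return an object of class `mixture`.
#' @examples
#' mixture(c("CCO", "O"), c(2, 1), label = 1)
#' @export
mixture <- function(smiles, coef, label = NA_integer_, names = NULL) {
  smiles <- as.character(smiles)
  coef <- as.integer(coef)
  if (length(smiles) < 1L) stop_ns("a mixture needs at least one component")
  if (length(coef) != length(smiles))
    stop_ns("smiles and coef lengths differ (%d vs %d)", length(smiles), length(coef))
  if (anyNA(coef) || any(coef < 1L))
    stop_ns("stoichiometric coefficients must be positive integers")
  if (!is.na(label)) assert_flag01(label)
  structure(list(smiles = smiles, coef = coef,
                 label = if (is.na(label)) NA_integer_ else as.integer(label),
                 names = names),
            class = "mixture")
}

#' @export
print.mixture <- function(x, ...) {
  cat(sprintf("<mixture> %s  label=%s\n",
              paste(sprintf("%d x %s", x$coef, x$smiles), collapse = " + "),
              ifelse(is.na(x$label), "?", x$label)))
  invisible(x)
}

# canonical multiset identity: exact (SMILES, coefficient) pairs, order-free,
# no ratio rescaling (1:1:1 and 4:1:1 of the same compounds are distinct).
mixture_key <- function(m) {
  paste(sort_c(paste0(m$smiles, "#", m$coef)), collapse = "|")
}

mixture_keys <- function(mixtures) vapply(mixtures, mixture_key, character(1L))

mixture_labels <- function(mixtures) {
  vapply(mixtures, function(m) as.integer(m$label), integer(1L))
}

#' Encode a mixture as a single-line string
#'
#' Components are sorted lexicographically (byte order) by SMILES so the
#' encoding is invariant under component permutation; each component is
#' rendered as its ratio token `[Rc]` followed by its SMILES, and components
#' are joined with ".".
#'
#' @param m a [mixture()].
#' @return single-line character string with no whitespace.
#' @examples
#' encode_mixture(mixture(c("O", "CCO"), c(1, 2)))  # "[R2]CCO.[R1]O"
#' @export
encode_mixture <- function(m) {
  stopifnot(inherits(m, "mixture"))
  if (length(m$smiles) == 0L) stop_ns("cannot encode an empty mixture")
  if (any(m$coef < 1L | m$coef > 10L))
    stop_ns("coefficient out of range 1..10: %s",
            paste(m$coef[m$coef < 1L | m$coef > 10L], collapse = ", "))
  ord <- order_c(m$smiles, m$coef)
  paste0("[R", m$coef[ord], "]", m$smiles[ord], collapse = ".")
}

#' Decode an encoded mixture string
#'
#' Inverse of [encode_mixture()] up to component ordering.  Component names
#' are resolved against an optional compound library; SMILES absent from the
#' library yield anonymous components.
#'
#' @param text encoded mixture string, e.g. `"[R2]CCO.[R1]O"`.
#' @param library optional compound library (`data.frame` with columns
#'   `name`, `smiles`).
#' @return a [mixture()] (unlabeled).
#' @export
decode_mixture <- function(text, library = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  parts <- strsplit(text, ".", fixed = TRUE)[[1]]
  if (length(parts) == 0L) stop_ns("malformed encoded mixture: empty string")
  mm <- regmatches(parts, regexec("^\\[R(10|[1-9])\\](.+)$", parts))
  bad <- vapply(mm, length, integer(1L)) != 3L
  if (any(bad))
    stop_ns("malformed encoded mixture near %s (missing or bad ratio token)",
            sQuote(parts[which(bad)[1]]))
  coef <- as.integer(vapply(mm, `[[`, character(1L), 2L))
  smiles <- vapply(mm, `[[`, character(1L), 3L)
  names <- NULL
  if (!is.null(library)) {
    idx <- match(smiles, library$smiles)
    names <- ifelse(is.na(idx), NA_character_, library$name[idx])
  }
  mixture(smiles, coef, names = names)
}

decode_mixtures <- function(texts, library = NULL) {
  lapply(texts, decode_mixture, library = library)
}

# ---- file dialects ---------------------------------------------------------

#' Read / write a compound library
#'
#' CSV with header `name,smiles`.
#'
#' @param path file path.
#' @return `data.frame` with columns `name` and `smiles`.
#' @export
read_compound_library <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("name", "smiles") %in% names(df)))
    stop_ns("compound library %s must have header 'name,smiles'", path)
  df[, c("name", "smiles")]
}

#' @rdname read_compound_library
#' @param library `data.frame` with columns `name` and `smiles`.
#' @export
write_compound_library <- function(library, path) {
  utils::write.csv(library[, c("name", "smiles")], path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read / write a labeled mixture dataset
#'
#' Two dialects are supported.  The wide dialect has header
#' `smiles_1,coef_1,...,smiles_n,coef_n,label` with ragged rows (each row
#' lists its own components, label last).  The encoded dialect has header
#' `encoded,label` with one [encode_mixture()] string per row.
#'
#' @param path file path.
#' @return a list of labeled [mixture()] objects.
#' @export
read_mixture_db <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 1L) stop_ns("empty mixture dataset: %s", path)
  header <- strsplit(lines[[1]], ",", fixed = TRUE)[[1]]
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (identical(header, c("encoded", "label"))) {
    out <- lapply(body, function(ln) {
      f <- strsplit(ln, ",", fixed = TRUE)[[1]]
      if (length(f) != 2L) stop_ns("bad row in %s: %s", path, sQuote(ln))
      m <- decode_mixture(f[[1]])
      m$label <- assert_flag01(as.integer(f[[2]]))
      m
    })
    return(out)
  }
  if (!identical(header[1:2], c("smiles_1", "coef_1")))
    stop_ns("unrecognized mixture dataset header in %s", path)
  lapply(body, function(ln) {
    f <- strsplit(ln, ",", fixed = TRUE)[[1]]
    if (length(f) < 3L || length(f) %% 2L != 1L)
      stop_ns("bad row in %s: %s", path, sQuote(ln))
    k <- (length(f) - 1L) %/% 2L
    smiles <- f[2L * seq_len(k) - 1L]
    coef <- as.integer(f[2L * seq_len(k)])
    mixture(smiles, coef, label = assert_flag01(as.integer(f[[length(f)]])))
  })
}

#' @rdname read_mixture_db
#' @param mixtures list of labeled [mixture()] objects.
#' @param dialect `"wide"` (default) or `"encoded"`.
#' @export
write_mixture_db <- function(mixtures, path, dialect = c("wide", "encoded")) {
  dialect <- match.arg(dialect)
  if (dialect == "encoded") {
    rows <- vapply(mixtures, function(m)
      paste0(encode_mixture(m), ",", m$label), character(1L))
    writeLines(c("encoded,label", rows), path, useBytes = TRUE)
  } else {
    kmax <- max(vapply(mixtures, function(m) length(m$smiles), integer(1L)))
    header <- paste(c(rbind(paste0("smiles_", seq_len(kmax)),
                            paste0("coef_", seq_len(kmax)))[seq_len(2L * kmax)],
                      "label"), collapse = ",")
    rows <- vapply(mixtures, function(m) {
      paste(c(rbind(m$smiles, m$coef), m$label), collapse = ",")
    }, character(1L))
    writeLines(c(header, rows), path, useBytes = TRUE)
  }
  invisible(path)
}
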