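# SMILES canonicalization behind a pluggable contract.
#
# The package core never requires a chemistry engine: every function that
# needs canonical SMILES takes a `canonicalizer`, a function mapping a
# character vector of SMILES to a character vector of canonical SMILES,
# erroring on unparseable input.  Two implementations are provided: a
# syntax-checking identity fallback and an RDKit bridge (via the `python`
# interpreter, when one with rdkit is on the PATH).

# Light structural validation: character set, balanced branches/brackets,
# paired ring-bond digits.  This is not a SMILES parser; it rejects the
# obviously malformed strings (e.g. "C(") while accepting all strings the
# synthetic grammar and standard organic-subset SMILES produce.
validate_smiles_syntax <- function(smiles) {
  ok <- nzchar(smiles) &
    !grepl("[^A-Za-z0-9@+\\-\\[\\]()=#$%:./\\\\]", smiles)
  bal <- function(x, open, close) {
    chars <- strsplit(x, "", fixed = TRUE)
    vapply(chars, function(cc) {
      depth <- cumsum((cc == open) - (cc == close))
      all(depth >= 0L) && utils::tail(depth, 1L) == 0L
    }, logical(1L))
  }
  ok <- ok & bal(smiles, "(", ")") & bal(smiles, "[", "]")
  # ring-closure digits outside brackets must come in pairs
  ring_ok <- vapply(smiles, function(s) {
    s2 <- gsub("\\[[^]]*\\]", "", s)
    digs <- regmatches(s2, gregexpr("%[0-9]{2}|[0-9]", s2))[[1]]
    all(table(digs) %% 2L == 0L)
  }, logical(1L), USE.NAMES = FALSE)
  ok & ring_ok
}

#' Identity canonicalizer (syntax-checking fallback)
#'
#' Returns a canonicalizer that validates SMILES syntax and returns the input
#' unchanged.  Used when no chemistry engine is available; under this contract
#' "canonical SMILES" means "the string as written", and idempotence holds
#' trivially.  The fallback announces itself once so logs record that no
#' chemical normalization took place.
#'
#' @param quiet suppress the one-time fallback notice.
#' @return a function `character -> character` erroring on malformed input.
#' @seealso [rdkit_canonicalizer()], [canonicalize_smiles()]
#' @export
identity_canonicalizer <- function(quiet = FALSE) {
  if (!quiet)
    log_msg("canonicalizer: identity fallback (no chemistry engine); SMILES are syntax-checked only")
  function(smiles) {
    smiles <- as.character(smiles)
    ok <- validate_smiles_syntax(smiles)
    if (!all(ok))
      stop_ns("unparseable SMILES: %s",
              paste(sQuote(utils::head(smiles[!ok], 5L)), collapse = ", "))
    smiles
  }
}

#' RDKit canonicalizer (via a python interpreter)
#'
#' Bridges to RDKit's `Chem.CanonSmiles` through an external `python`
#' process.  Input is passed one SMILES per line on stdin and canonical
#' SMILES are read back in order, so a single call canonicalizes a whole
#' vector at once.
#'
#' @param python path to a python interpreter with rdkit importable.
#' @return a canonicalizer function, or an error if rdkit is unavailable.
#' @export
rdkit_canonicalizer <- function(python = Sys.which("python")) {
  if (!nzchar(python))
    stop_ns("no python interpreter found for the RDKit canonicalizer")
  script <- paste(
    "import sys",
    "from rdkit import Chem",
    "from rdkit import RDLogger",
    "RDLogger.DisableLog('rdApp.*')",
    "for line in sys.stdin:",
    "    s = line.rstrip('\\n')",
    "    m = Chem.MolFromSmiles(s)",
    "    if m is None:",
    "        sys.stdout.write('\\x01ERR\\t' + s + '\\n')",
    "    else:",
    "        sys.stdout.write(Chem.MolToSmiles(m) + '\\n')",
    sep = "\n")
  probe <- suppressWarnings(system2(python, c("-c", shQuote("import rdkit")),
                                    stdout = TRUE, stderr = TRUE))
  if (!is.null(attr(probe, "status")) && attr(probe, "status") != 0L)
    stop_ns("rdkit is not importable from %s", python)
  function(smiles) {
    smiles <- as.character(smiles)
    if (length(smiles) == 0L) return(character(0))
    if (any(grepl("[\n\r]", smiles)))
      stop_ns("unparseable SMILES: embedded newline")
    out <- system2(python, c("-c", shQuote(script)),
                   input = smiles, stdout = TRUE, stderr = FALSE)
    if (length(out) != length(smiles))
      stop_ns("RDKit bridge returned %d lines for %d inputs", length(out), length(smiles))
    bad <- startsWith(out, "\x01ERR\t")
    if (any(bad))
      stop_ns("unparseable SMILES: %s",
              paste(sQuote(sub("^\x01ERR\t", "", utils::head(out[bad], 5L))), collapse = ", "))
    out
  }
}

#' Canonicalize SMILES strings
#'
#' Applies the plugged canonicalizer.  The contract demands determinism and
#' idempotence: `canonicalize_smiles(canonicalize_smiles(x)) ==
#' canonicalize_smiles(x)`.
#'
#' @param smiles character vector of SMILES.
#' @param canonicalizer a canonicalizer function; defaults to the
#'   syntax-checking identity fallback.
#' @return character vector of canonical SMILES.
#' @examples
#' canonicalize_smiles("CCO")
#' @export
canonicalize_smiles <- function(smiles, canonicalizer = identity_canonicalizer(quiet = TRUE)) {
  canonicalizer(as.character(smiles))
}
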