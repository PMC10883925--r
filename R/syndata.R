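# Synthetic stand-ins for the two unavailable inputs: the ~1e6-reaction
# pre-training corpus and the ~1000-mixture labeled NADES/DES database.
#
# The synthetic world consists of a 198-compound library of valid-by-
# construction linear-chain SMILES over C/O/N, one designated marker
# compound (playing the screening role ibuprofen plays against the real
# model), and a deterministic latent stability rule that is visible in the
# encoded token stream:
#
#   stable(m) = 1  iff  o_lo <= sum_i c_i * nO_i <= o_hi  and
#                       sum_i c_i * nN_i >= n_min
#
# where c_i are the stoichiometric coefficients and nO_i / nN_i the oxygen /
# nitrogen atom counts of component i.  Because coefficients appear as ratio
# tokens and heteroatoms as O/N tokens, the rule is decidable from the
# encoded string alone, so a token-level model can in principle learn it.
# Default rule parameters are chosen once (see the methods vignette): the
# nitrogen minimum is the active constraint for 2-3-component literature-like
# mixtures (hydrogen-bond-acceptor proxy), while the oxygen window caps the
# coefficient-heavy tail that dominates random 3-5-component mixtures.

MARKER_SMILES <- "CC(C)CC(O)CC(C)O"  # synthetic ibuprofen stand-in (no N, 2 O)
MARKER_NAME <- "synthetic-marker (ibuprofen stand-in)"

#' Generate the synthetic compound library
#'
#' Builds `n` unique SMILES from a grammar of atom chains (length 3-9) over
#' \{C, O, N\} with optional single-atom branches on interior carbons; every
#' string is valid by construction (single bonds only, valence-safe).  A
#' fixed fraction of compounds carry 1-2 nitrogen atoms (amine-like), the
#' rest are C/O-only (sugar-/polyol-like), mirroring the hydrogen-bond
#' donor/acceptor make-up of real NADES component lists.  The first entry is
#' always the fixed marker compound.
#'
#' @param n library size (default 198); at least 6.
#' @param seed integer seed.
#' @param p_amine probability a compound carries nitrogen (default 0.12).
#' @param p_oxygen per-position probability of O rather than C (default 0.35).
#' @return `data.frame` with columns `name`, `smiles` and provenance columns
#'   `n_O`, `n_N` (heteroatom counts).
#' @export
make_compound_library <- function(n = 198L, seed = 1L, p_amine = 0.12,
                                  p_oxygen = 0.35) {
  n <- as.integer(n)
  if (n < 6L) stop_ns("library needs at least 6 compounds (got %d)", n)
  gen_one <- function() {
    len <- sample(3:9, 1L)
    atoms <- ifelse(stats::runif(len) < p_oxygen, "O", "C")
    if (stats::runif(1) < p_amine) {
      n_n <- sample(1:2, 1L)
      pos <- sample.int(len, min(n_n, len))
      atoms[pos] <- "N"
    }
    out <- character(0)
    for (i in seq_along(atoms)) {
      out <- c(out, atoms[i])
      if (i > 1L && i < len && atoms[i] == "C" && stats::runif(1) < 0.25)
        out <- c(out, "(", sample(c("C", "O"), 1L), ")")
    }
    paste(out, collapse = "")
  }
  with_seed(seed, {
    smiles <- MARKER_SMILES
    attempts <- 0L
    while (length(smiles) < n) {
      s <- gen_one()
      attempts <- attempts + 1L
      if (attempts > 200L * n)
        stop_ns("compound grammar exhausted after %d attempts for n = %d", attempts, n)
      if (!s %in% smiles) smiles <- c(smiles, s)
    }
    data.frame(
      name = c(MARKER_NAME, sprintf("synthetic-compound-%03d", seq_len(n - 1L))),
      smiles = smiles,
      n_O = count_atom(smiles, "O"),
      n_N = count_atom(smiles, "N"),
      stringsAsFactors = FALSE)
  })
}

# atom counts for the branchless-bracket grammar: plain character counts
count_atom <- function(smiles, atom) {
  vapply(strsplit(smiles, "", fixed = TRUE),
         function(cc) sum(cc == atom), integer(1L))
}

#' Assemble the synthetic world
#'
#' Bundles the compound library with the latent-rule parameters.
#'
#' @param n_compounds library size (default 198).
#' @param seed integer seed.
#' @param o_lo,o_hi inclusive window on the coefficient-weighted oxygen
#'   count (defaults 2 and 90).
#' @param n_min minimum coefficient-weighted nitrogen count (default 1).
#' @return object of class `synthetic_world` with elements `library`,
#'   `rule`, `marker`, `seed`.
#' @export
synthetic_world <- function(n_compounds = 198L, seed = 1L,
                            o_lo = 2, o_hi = 90, n_min = 1) {
  if (!(o_lo <= o_hi) || n_min < 0) stop_ns("invalid rule parameters")
  structure(list(library = make_compound_library(n_compounds, seed = seed),
                 rule = list(o_lo = o_lo, o_hi = o_hi, n_min = n_min),
                 marker = MARKER_SMILES,
                 seed = as.integer(seed)),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world> %d compounds; rule: %g <= sum(c*O) <= %g & sum(c*N) >= %g\n",
              nrow(x$library), x$rule$o_lo, x$rule$o_hi, x$rule$n_min))
  invisible(x)
}

#' Latent stability rule
#'
#' Deterministic ground-truth label of a mixture under the synthetic world:
#' stable iff the coefficient-weighted oxygen count lies in `[o_lo, o_hi]`
#' and the coefficient-weighted nitrogen count reaches `n_min`.
#'
#' @param m a [mixture()] whose components all belong to the world library.
#' @param world a [synthetic_world()] (or a list with `library` and `rule`).
#' @return integer 0 or 1.
#' @export
latent_stability <- function(m, world) {
  idx <- match(m$smiles, world$library$smiles)
  if (anyNA(idx))
    stop_ns("unknown compound(s) not in world library: %s",
            paste(sQuote(m$smiles[is.na(idx)]), collapse = ", "))
  sum_o <- sum(m$coef * world$library$n_O[idx])
  sum_n <- sum(m$coef * world$library$n_N[idx])
  r <- world$rule
  as.integer(sum_o >= r$o_lo && sum_o <= r$o_hi && sum_n >= r$n_min)
}

# vectorized rule over index/coefficient matrices (rows = mixtures)
latent_stability_matrix <- function(comp_idx, coef, world) {
  nO <- world$library$n_O; nN <- world$library$n_N
  wO <- coef * matrix(nO[comp_idx], nrow(comp_idx), ncol(comp_idx))
  wN <- coef * matrix(nN[comp_idx], nrow(comp_idx), ncol(comp_idx))
  sum_o <- rowSums(wO, na.rm = TRUE)
  sum_n <- rowSums(wN, na.rm = TRUE)
  r <- world$rule
  as.integer(sum_o >= r$o_lo & sum_o <= r$o_hi & sum_n >= r$n_min)
}

#' Generate the labeled synthetic mixture database
#'
#' Rejection-samples random 2-3-component mixtures (coefficients 1-10,
#' components drawn without replacement) until exactly `n_stable`
#' rule-positive and `n - n_stable` rule-negative unique mixtures are
#' collected.  Labels are assigned by [latent_stability()], so every stored
#' record is consistent with the rule by construction.
#'
#' @param world a [synthetic_world()].
#' @param n total records (default 1000).
#' @param n_stable stable records (default 800, the 4:1 literature
#'   imbalance).
#' @param seed integer seed.
#' @param k_range component-count range (default 2:3, literature-like).
#' @param coef_range coefficient range (default 1:10).
#' @param max_draws rejection cap (default `500 * n`).
#' @return list of labeled [mixture()] objects, shuffled.
#' @export
make_labeled_db <- function(world, n = 1000L, n_stable = 800L, seed = 1L,
                            k_range = 2:3, coef_range = 1:10,
                            max_draws = 500L * n) {
  stopifnot(inherits(world, "synthetic_world"))
  n <- as.integer(n); n_stable <- as.integer(n_stable)
  if (n_stable > n || n_stable < 0L) stop_ns("need 0 <= n_stable <= n")
  lib <- world$library
  with_seed(seed, {
    pos <- list(); neg <- list()
    seen <- new.env(hash = TRUE, parent = emptyenv())
    draws <- 0L
    while (length(pos) < n_stable || length(neg) < n - n_stable) {
      if (draws >= max_draws) {
        acc <- (length(pos) + length(neg)) / max(draws, 1L)
        stop_ns(paste0("rejection cap (%d draws) exceeded with %d/%d stable and ",
                       "%d/%d unstable collected (acceptance rate %.3f); ",
                       "the rule may be unsatisfiable in the generator ranges"),
                max_draws, length(pos), n_stable, length(neg), n - n_stable, acc)
      }
      draws <- draws + 1L
      k <- sample_vec(k_range, 1L)
      idx <- sample.int(nrow(lib), k)
      cf <- sample_vec(coef_range, k, replace = TRUE)
      m <- mixture(lib$smiles[idx], cf, names = lib$name[idx])
      key <- mixture_key(m)
      if (!is.null(seen[[key]])) next
      lab <- latent_stability(m, world)
      if (lab == 1L && length(pos) < n_stable) {
        m$label <- 1L; pos[[length(pos) + 1L]] <- m; seen[[key]] <- TRUE
      } else if (lab == 0L && length(neg) < n - n_stable) {
        m$label <- 0L; neg[[length(neg) + 1L]] <- m; seen[[key]] <- TRUE
      }
    }
    db <- c(pos, neg)
    db[sample.int(length(db))]
  })
}

#' Generate a synthetic reaction corpus
#'
#' Each line is `A.B>C` where `A` and `B` are library SMILES and `C` is a
#' deterministic string edit of `A` (a terminal "oxidation": `C = A + "O"`),
#' so the corpus has learnable token statistics and every line contains
#' exactly one ">".
#'
#' @param world a [synthetic_world()].
#' @param n_lines number of corpus lines.
#' @param seed integer seed.
#' @return character vector of corpus lines.
#' @export
make_reaction_corpus <- function(world, n_lines = 500L, seed = 1L) {
  stopifnot(inherits(world, "synthetic_world"), n_lines >= 1L)
  lib <- world$library$smiles
  with_seed(seed, {
    a <- sample(lib, n_lines, replace = TRUE)
    b <- sample(lib, n_lines, replace = TRUE)
    paste0(a, ".", b, ">", a, "O")
  })
}
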