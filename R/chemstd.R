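#' Iterative chemical standardization
#'
#' Standardizes raw SMILES into a canonical, physiological-pH representation
#' used as the identity of a compound throughout the pipeline. Each iteration
#' applies molecular cleanup (largest organic fragment), charge
#' neutralization, a small fixed set of representation-normalization rules
#' (charge-separated nitro/azide/N-oxide forms), and canonicalization, and the
#' cycle repeats until the canonical SMILES reaches a fixed point or
#' \code{max_iterations} is exhausted. If the cycle does not converge, the
#' most frequently observed SMILES across iterations is chosen (ties broken
#' toward the lexicographically smallest). Protonation at \code{ph} is applied
#' once, after the loop, so that neutralization cannot undo it; the standard
#' InChI is then derived from the protonated canonical SMILES.
#'
#' @param smiles character vector of raw SMILES.
#' @param max_iterations maximum number of standardization cycles (>= 1).
#' @param ph pH at which the final protonation state is assigned.
#' @return A data.frame with one row per input and columns
#'   \code{raw_smiles}, \code{std_smiles}, \code{std_inchi},
#'   \code{n_iterations}, \code{converged}.
#' @examples
#' \donttest{
#' standardize_compounds(c("C(C)O", "CC(=O)O", "CCN(CC)CC"))
#' }
#' @export
standardize_compounds <- function(smiles, max_iterations = 5L, ph = 7.4) {
  stopifnot(is.character(smiles), max_iterations >= 1L)
  if (length(smiles) == 0L) {
    return(data.frame(raw_smiles = character(), std_smiles = character(),
                      std_inchi = character(), n_iterations = integer(),
                      converged = logical()))
  }
  if (any(is.na(smiles) | !nzchar(trimws(smiles)))) {
    stop("empty SMILES at position(s): ",
         paste(which(is.na(smiles) | !nzchar(trimws(smiles))), collapse = ", "))
  }
  cur <- ob_convert(smiles, to = "CAN")
  if (anyNA(cur)) {
    bad <- smiles[is.na(cur)]
    stop("cannot standardize unparseable SMILES: ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) sprintf(" (and %d more)", length(bad) - 5L) else "")
  }
  n <- length(smiles)
  history <- vector("list", n)
  n_iter <- integer(n)
  converged <- logical(n)
  active <- seq_len(n)
  for (it in seq_len(max_iterations)) {
    nxt <- standardize_step(cur[active])
    if (anyNA(nxt)) {
      stop("standardization failed for: ",
           paste(cur[active][is.na(nxt)], collapse = ", "))
    }
    for (k in seq_along(active)) {
      history[[active[k]]] <- c(history[[active[k]]], nxt[k])
    }
    n_iter[active] <- it
    done <- nxt == cur[active]
    converged[active[done]] <- TRUE
    cur[active] <- nxt
    active <- active[!done]
    if (length(active) == 0L) break
  }
  # non-converged: most common SMILES across iterations, smallest on ties
  for (i in active) {
    tab <- table(history[[i]])
    modal <- names(tab)[tab == max(tab)]
    cur[i] <- sort(modal)[1L]
  }
  std <- ob_convert(cur, to = "CAN", ph = ph)
  fail <- is.na(std)
  std[fail] <- cur[fail]  # protonation engine declined; keep neutral form
  inchi <- ob_convert(std, to = "INCHI")
  if (anyNA(inchi)) {
    stop("InChI generation failed for: ", paste(std[is.na(inchi)], collapse = ", "))
  }
  data.frame(raw_smiles = smiles, std_smiles = std, std_inchi = inchi,
             n_iterations = n_iter, converged = converged,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Standardize a single compound
#'
#' Scalar convenience wrapper around [standardize_compounds()].
#'
#' @inheritParams standardize_compounds
#' @param raw_smiles a single SMILES string.
#' @return A one-row data.frame (see [standardize_compounds()]).
#' @export
standardize_compound <- function(raw_smiles, max_iterations = 5L, ph = 7.4) {
  stopifnot(length(raw_smiles) == 1L)
  standardize_compounds(raw_smiles, max_iterations = max_iterations, ph = ph)
}

# One cleanup -> neutralize -> normalize -> canonicalize cycle, vectorized.
standardize_step <- function(smiles) {
  cleaned <- vapply(smiles, largest_organic_fragment, "", USE.NAMES = FALSE)
  neutral <- ob_convert(cleaned, to = "CAN", neutralize = TRUE)
  neutral[is.na(neutral)] <- cleaned[is.na(neutral)]
  ob_convert(normalize_representation(neutral), to = "CAN")
}

# Fixed, order-independent representation normalizations applied between
# neutralization and canonicalization. Kept deliberately small: hypervalent
# nitro/azide/N-oxide spellings are rewritten to their charge-separated forms.
normalize_representation <- function(smiles) {
  rules <- c(
    "N(=O)=O"  = "[N+](=O)[O-]",
    "N(=O)(=O)" = "[N+](=O)[O-]",
    "N=N=N"    = "N=[N+]=[N-]"
  )
  for (from in names(rules)) {
    smiles <- gsub(from, rules[[from]], smiles, fixed = TRUE)
  }
  smiles
}

# Keep the largest organic fragment of a (possibly multi-component) SMILES.
# Organic = contains at least one carbon; largest by heavy-atom count, ties
# broken toward the lexicographically smallest fragment SMILES.
largest_organic_fragment <- function(smiles) {
  frags <- strsplit(smiles, ".", fixed = TRUE)[[1]]
  if (length(frags) == 1L) return(frags)
  organic <- contains_carbon(frags)
  pool <- if (any(organic)) frags[organic] else frags
  sizes <- count_heavy_atoms(pool)
  cand <- pool[sizes == max(sizes)]
  sort(cand)[1L]
}

#' Cross-dataset match key for a standardized compound
#'
#' The standard InChI of the standardized, pH-adjusted structure is the key
#' used for all joins and duplicate detection between datasets. Protomers and
#' representation variants of the same parent collapse to the same key
#' because they pass through the same standardization pipeline.
#'
#' @param std standardized compounds as returned by
#'   [standardize_compounds()], or a character vector of standard InChI.
#' @return character vector of match keys.
#' @export
match_key <- function(std) {
  if (is.data.frame(std)) {
    stopifnot("std_inchi" %in% names(std))
    return(std$std_inchi)
  }
  stopifnot(is.character(std))
  std
}
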