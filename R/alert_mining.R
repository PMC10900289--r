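#' Enumerate substructure fragments of a molecule
#'
#' Recursively cleaves acyclic single bonds (graph bridges of bond order 1),
#' keeping rings intact, and collects every connected fragment with a heavy
#' atom count within \code{[min_atoms, max_atoms]} (the parent molecule
#' included when it fits the bounds). Fragments are emitted as canonical
#' SMILES usable as SMARTS patterns: open valences become implicit
#' hydrogens, which under SMARTS semantics match any substitution, so every
#' fragment substructure-matches its parent.
#'
#' @param std_smiles a single valid SMILES.
#' @param min_atoms,max_atoms inclusive heavy-atom bounds (defaults 2 and 18).
#' @param exhaustive if TRUE, enumerate components over all subsets of
#'   cleavable bonds instead of recursive cleavage; identical output by
#'   construction, used as a test oracle on small molecules.
#' @return data.frame with columns \code{pattern}, \code{n_atoms}.
#' @export
enumerate_fragments <- function(std_smiles, min_atoms = 2L, max_atoms = 18L,
                                exhaustive = FALSE) {
  stopifnot(length(std_smiles) == 1L)
  enumerate_fragments_many(std_smiles, min_atoms, max_atoms, exhaustive)[[1]]
}

# Batched fragment enumeration: one SDF conversion for all molecules, pure-R
# graph recursion per molecule, then one batched canonicalization of all
# fragment subgraphs. Returns a list of data.frames aligned with `smiles`.
enumerate_fragments_many <- function(smiles, min_atoms = 2L, max_atoms = 18L,
                                     exhaustive = FALSE) {
  stopifnot(is.character(smiles), length(smiles) > 0L)
  if (anyNA(ob_convert(smiles, to = "CAN"))) {
    stop("invalid SMILES passed to fragment enumeration")
  }
  names(smiles) <- paste0("m", seq_along(smiles))
  sdfset <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  subsets <- vector("list", length(smiles))   # list of lists of atom index vectors
  for (i in seq_along(smiles)) {
    sdf <- sdfset[[i]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    elements <- sub("_.*", "", rownames(ab))
    heavy <- which(elements != "H")
    if (is.null(dim(bb)) || nrow(bb) == 0L) {
      subsets[[i]] <- if (length(heavy) >= min_atoms && length(heavy) <= max_atoms)
        list(heavy) else list()
      next
    }
    edges <- cbind(bb[, 1L], bb[, 2L])
    order1 <- bb[, 3L] == 1
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    if (length(igraph::V(g)) < nrow(ab)) {
      g <- igraph::add_vertices(g, nrow(ab) - length(igraph::V(g)))
    }
    bridge_ids <- igraph::bridges(g)
    is_h <- elements == "H"
    cuttable <- which(order1 &
                        seq_len(nrow(bb)) %in% as.integer(bridge_ids) &
                        !is_h[edges[, 1L]] & !is_h[edges[, 2L]])
    subsets[[i]] <- fragment_atom_sets(edges, cuttable, heavy, nrow(ab),
                                       min_atoms, max_atoms, exhaustive)
  }
  # batched conversion of all fragment subgraphs to canonical SMILES via a
  # hand-built molfile per subgraph (one Open Babel call for everything)
  blocks <- character(); owner <- integer(); sizes <- integer()
  for (i in seq_along(smiles)) {
    sdf <- sdfset[[i]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    bmat <- if (is.null(dim(bb))) matrix(bb, nrow = 1) else unname(as.matrix(bb))
    for (s in subsets[[i]]) {
      id <- sprintf("f%d", length(blocks) + 1L)
      blocks <- c(blocks, fragment_molfile(ab, bmat, s, id))
      owner <- c(owner, i)
      sizes <- c(sizes, length(s))
    }
  }
  out <- rep(list(data.frame(pattern = character(), n_atoms = integer())),
             length(smiles))
  if (length(blocks) == 0L) return(out)
  can <- ob_sdf_to_can(paste(blocks, collapse = ""), length(blocks))
  pat <- unname(can[paste0("f", seq_along(blocks))])
  if (anyNA(pat)) stop("fragment conversion failed")
  for (i in seq_along(smiles)) {
    sel <- owner == i
    d <- data.frame(pattern = pat[sel], n_atoms = sizes[sel],
                    stringsAsFactors = FALSE)
    d <- d[!duplicated(d$pattern), , drop = FALSE]
    rownames(d) <- NULL
    out[[i]] <- d
  }
  out
}

# V2000 molfile for the induced subgraph on atom set `s` (1-based indices
# into the atom block), with `id` on the title line for batch alignment.
fragment_molfile <- function(ab, bmat, s, id) {
  s <- sort(s)
  elements <- sub("_.*", "", rownames(ab))
  remap <- match(seq_len(nrow(ab)), s)
  keep_bonds <- which(bmat[, 1L] %in% s & bmat[, 2L] %in% s)
  atom_lines <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                        ab[s, 1L], ab[s, 2L], 0, elements[s])
  bond_lines <- if (length(keep_bonds)) {
    sprintf("%3d%3d%3d  0  0  0  0",
            remap[bmat[keep_bonds, 1L]], remap[bmat[keep_bonds, 2L]],
            bmat[keep_bonds, 3L])
  } else character(0)
  paste0(paste(c(id, "  dictox", "",
                 sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                         length(s), length(keep_bonds)),
                 atom_lines, bond_lines, "M  END", "$$$$"), collapse = "\n"), "\n")
}

# Collect heavy-atom index sets of fragments generated by cleaving bridge
# single bonds. `edges` is the full bond list; `cuttable` indexes cleavable
# bonds; `heavy` lists non-hydrogen atom indices.
fragment_atom_sets <- function(edges, cuttable, heavy, n_atoms,
                               min_atoms, max_atoms, exhaustive) {
  # connected components among `members` using only `keep_edges`; plain BFS
  # over adjacency lists (called heavily in the recursion, so no igraph here)
  comp_of <- function(keep_edges, members) {
    adj <- vector("list", n_atoms)
    for (e in keep_edges) {
      a <- edges[e, 1L]; b <- edges[e, 2L]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
    unseen <- rep(FALSE, n_atoms)
    unseen[members] <- TRUE
    out <- list()
    for (start in members) {
      if (!unseen[start]) next
      queue <- start
      unseen[start] <- FALSE
      comp <- integer(0)
      while (length(queue)) {
        v <- queue[[1L]]; queue <- queue[-1L]
        comp <- c(comp, v)
        nb <- adj[[v]]
        nb <- nb[unseen[nb]]
        unseen[nb] <- FALSE
        queue <- c(queue, nb)
      }
      out[[length(out) + 1L]] <- comp
    }
    out
  }
  seen <- new.env(parent = emptyenv())
  result <- list()
  add_set <- function(s) {
    s <- sort(intersect(s, heavy))
    key <- paste(s, collapse = ",")
    if (!is.null(seen[[key]])) return(FALSE)
    seen[[key]] <- TRUE
    if (length(s) >= min_atoms && length(s) <= max_atoms) {
      result[[length(result) + 1L]] <<- s
    }
    TRUE
  }
  all_edges <- seq_len(nrow(edges))
  if (exhaustive) {
    k <- length(cuttable)
    if (k > 20L) stop("exhaustive mode is limited to molecules with <= 20 cleavable bonds")
    for (mask in 0:(2^k - 1L)) {
      cut <- cuttable[bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0]
      for (comp in comp_of(setdiff(all_edges, cut), heavy)) add_set(comp)
    }
    return(result)
  }
  recurse <- function(atom_set, edge_set) {
    if (!add_set(atom_set)) return(invisible())
    inner <- edge_set[edge_set %in% cuttable]
    for (e in inner) {
      pieces <- comp_of(setdiff(edge_set, e), intersect(atom_set, heavy))
      for (piece in pieces) {
        sub_edges <- edge_set[edges[edge_set, 1L] %in% piece &
                                edges[edge_set, 2L] %in% piece]
        recurse(piece, sub_edges)
      }
    }
  }
  start_edges <- all_edges
  for (comp in comp_of(start_edges, heavy)) {
    sub_edges <- start_edges[edges[start_edges, 1L] %in% comp &
                               edges[start_edges, 2L] %in% comp]
    recurse(comp, sub_edges)
  }
  result
}

#' Mine structural alerts from a labeled dataset
#'
#' Pools fragments from the compounds selected by each mining setting
#' (\code{all_compounds}: every compound; \code{toxic_only}: label-1
#' compounds), then counts, over the full scheme dataset, the compounds
#' containing each fragment (substructure match, per-compound binary
#' counting) and how many of those are toxic. Fragments occurring at least
#' \code{min_occurrence} times are retained with their positive predictive
#' value PPV = positives / occurrences.
#'
#' Schemes: \code{binary_label} contrasts toxic (label 1) against nontoxic
#' (label 0); \code{most_concern} contrasts most-concern (positive) against
#' no-concern (negative), excluding less-concern compounds from the
#' denominators.
#'
#' @param ds data.frame with \code{key}, \code{std_smiles}, \code{label} and
#'   (for \code{most_concern}) \code{concern}.
#' @param min_occurrence minimum per-compound occurrence count (default 5).
#' @param setting one or both of \code{"all_compounds"}, \code{"toxic_only"}.
#' @param scheme \code{"binary_label"} or \code{"most_concern"}.
#' @param min_atoms,max_atoms fragment size bounds (defaults 2 and 18).
#' @return data.frame of alerts: \code{pattern, n_atoms, occurrences,
#'   positives, ppv, setting, scheme}.
#' @export
mine_alerts <- function(ds, min_occurrence = 5L,
                        setting = c("all_compounds", "toxic_only"),
                        scheme = c("binary_label", "most_concern"),
                        min_atoms = 2L, max_atoms = 18L) {
  scheme <- match.arg(scheme)
  setting <- match.arg(setting, several.ok = TRUE)
  stopifnot(is.data.frame(ds), all(c("std_smiles", "label") %in% names(ds)))
  if (scheme == "most_concern") {
    stopifnot("concern" %in% names(ds))
    ds <- ds[ds$concern %in% c("most", "no"), , drop = FALSE]
    ds$label <- ifelse(ds$concern == "most", 1L, 0L)
  } else {
    ds <- ds[!is.na(ds$label), , drop = FALSE]
  }
  if (nrow(ds) == 0L) stop("empty dataset under scheme ", scheme)
  frags <- enumerate_fragments_many(ds$std_smiles, min_atoms, max_atoms)
  pool_patterns <- function(idx) {
    do.call(rbind, frags[idx])
  }
  pools <- lapply(setting, function(st) {
    idx <- if (st == "toxic_only") which(ds$label == 1L) else seq_len(nrow(ds))
    p <- pool_patterns(idx)
    if (is.null(p)) p <- data.frame(pattern = character(), n_atoms = integer())
    p[!duplicated(p$pattern), , drop = FALSE]
  })
  names(pools) <- setting
  all_pat <- do.call(rbind, pools)
  all_pat <- all_pat[!duplicated(all_pat$pattern), , drop = FALSE]
  counts <- count_pattern_hits(all_pat$pattern, ds$std_smiles, ds$label)
  rownames(counts) <- all_pat$pattern
  out <- lapply(setting, function(st) {
    p <- pools[[st]]
    cc <- counts[p$pattern, , drop = FALSE]
    keep <- cc[, "occurrences"] >= min_occurrence
    data.frame(pattern = p$pattern[keep], n_atoms = p$n_atoms[keep],
               occurrences = cc[keep, "occurrences"],
               positives = cc[keep, "positives"],
               ppv = cc[keep, "positives"] / cc[keep, "occurrences"],
               setting = st, scheme = scheme,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

# Compound-by-pattern substructure hit matrix. With `prescreen` (default) a
# pattern is SMARTS-verified only on molecules whose FP2 path-fingerprint
# contains every path bit of the pattern — a necessary condition for a
# substructure match, so the screen removes no true hit; prescreen = FALSE
# is the exact reference path used to verify that equivalence in the tests.
substructure_hit_matrix <- function(patterns, smiles, prescreen = TRUE) {
  hits <- matrix(FALSE, nrow = length(smiles), ncol = length(patterns),
                 dimnames = list(NULL, patterns))
  if (length(patterns) == 0L || length(smiles) == 0L) return(hits)
  mols <- ob_parse(smiles)
  cand <- if (prescreen) {
    # one call for both sides so pattern and molecule bits are guaranteed to
    # come from the same fingerprint computation
    fp <- ob_fp2_matrix(c(patterns, smiles))
    fpp <- fp[seq_along(patterns), , drop = FALSE]
    fpm <- fp[length(patterns) + seq_along(smiles), , drop = FALSE]
    fpp %*% t(1 - fpm) == 0   # no pattern bit missing from the molecule
  } else {
    matrix(TRUE, length(patterns), length(smiles))
  }
  for (i in seq_along(patterns)) {
    idx <- which(cand[i, ])
    if (length(idx) == 0L) next
    hit <- ChemmineOB::smartsSearch_OB(mols[idx], patterns[i],
                                       uniqueMatches = TRUE) > 0
    hits[idx[hit], i] <- TRUE
  }
  hits
}

# Per-compound binary occurrence counting of SMARTS patterns.
count_pattern_hits <- function(patterns, smiles, labels, prescreen = TRUE) {
  if (length(patterns) == 0L) {
    return(matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("occurrences", "positives"))))
  }
  hits <- substructure_hit_matrix(patterns, smiles, prescreen)
  cbind(occurrences = colSums(hits),
        positives = colSums(hits & labels == 1L))
}

#' Filter and merge alert lists from the two mining settings
#'
#' Union by pattern (on collision the record with the higher occurrence
#' count wins), then drop alerts with PPV below \code{min_ppv}, alerts with
#' fewer than \code{min_atoms_keep} atoms, and generic scaffolds on the
#' blocklist (default: benzene).
#'
#' @param alerts_a,alerts_b alert data.frames from [mine_alerts()]
#'   (\code{alerts_b} may be NULL if \code{alerts_a} already carries both
#'   settings).
#' @param min_ppv minimum positive predictive value (default 0.5).
#' @param min_atoms_keep minimum fragment size kept (default 5, i.e. alerts
#'   with four or fewer atoms are removed).
#' @param blocklist SMILES of generic scaffolds to exclude.
#' @return merged, filtered alert data.frame.
#' @export
filter_and_merge <- function(alerts_a, alerts_b = NULL, min_ppv = 0.5,
                             min_atoms_keep = 5L, blocklist = "c1ccccc1") {
  alerts <- rbind(alerts_a, alerts_b)
  if (is.null(alerts) || nrow(alerts) == 0L) {
    return(alerts_a[0, , drop = FALSE])
  }
  alerts <- alerts[order(-alerts$occurrences, alerts$pattern), , drop = FALSE]
  alerts <- alerts[!duplicated(alerts$pattern), , drop = FALSE]
  blocked <- ob_convert(blocklist, to = "CAN")
  norm <- ob_convert(alerts$pattern, to = "CAN")
  norm[is.na(norm)] <- alerts$pattern[is.na(norm)]
  keep <- alerts$ppv >= min_ppv &
    alerts$n_atoms >= min_atoms_keep &
    !(norm %in% blocked)
  out <- alerts[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screen compounds against structural alerts
#'
#' Lists, per compound, the alert patterns it contains. Compounds whose key
#' appears in \code{exclude_keys} (e.g. overlapping a training set) are
#' skipped and counted, never screened — this prevents information leaking
#' into retrospective analyses.
#'
#' @param compounds data.frame with \code{key} and \code{std_smiles}, or a
#'   character vector of SMILES (keys default to the SMILES).
#' @param alerts alert data.frame with a \code{pattern} column.
#' @param exclude_keys keys to skip.
#' @return data.frame \code{key, std_smiles, n_hits, patterns}
#'   (comma-separated matched patterns; zero-hit rows retained). The number
#'   of skipped compounds is attached as attribute \code{"n_skipped"}.
#' @export
screen_compounds <- function(compounds, alerts, exclude_keys = character()) {
  if (is.character(compounds)) {
    compounds <- data.frame(key = compounds, std_smiles = compounds,
                            stringsAsFactors = FALSE)
  }
  stopifnot(all(c("key", "std_smiles") %in% names(compounds)))
  skip <- compounds$key %in% exclude_keys
  n_skipped <- sum(skip)
  if (n_skipped > 0L) {
    message("screen_compounds: skipping ", n_skipped,
            " compound(s) overlapping the excluded key set")
  }
  compounds <- compounds[!skip, , drop = FALSE]
  if (nrow(compounds) == 0L) {
    out <- data.frame(key = character(), std_smiles = character(),
                      n_hits = integer(), patterns = character())
    attr(out, "n_skipped") <- n_skipped
    return(out)
  }
  parsed <- ob_convert(alerts$pattern, to = "SMI")
  if (anyNA(parsed)) {
    stop("invalid alert pattern: ",
         paste(alerts$pattern[is.na(parsed)], collapse = ", "))
  }
  hits <- substructure_hit_matrix(alerts$pattern, compounds$std_smiles)
  out <- data.frame(
    key = compounds$key, std_smiles = compounds$std_smiles,
    n_hits = rowSums(hits),
    patterns = apply(hits, 1, function(h) paste(alerts$pattern[h], collapse = ",")),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_skipped") <- n_skipped
  out
}
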