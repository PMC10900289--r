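#' Binarize cardiotoxicity concern categories
#'
#' Maps the three informative DICT concern categories onto the binary label
#' used by the classifiers: \code{most} and \code{less} concern become 1,
#' \code{no} concern becomes 0, and \code{ambiguous} compounds are excluded
#' (returned as \code{NA}, the excluded marker).
#'
#' @param concern character vector with values in
#'   \code{c("most", "less", "no", "ambiguous")}.
#' @return integer vector of 0/1 labels with \code{NA} for excluded rows.
#' @export
binarize_concern <- function(concern) {
  stopifnot(is.character(concern) | is.factor(concern))
  concern <- as.character(concern)
  valid <- c("most", "less", "no", "ambiguous")
  if (!all(concern %in% valid)) {
    stop("unrecognized concern category: ",
         paste(unique(setdiff(concern, valid)), collapse = ", "))
  }
  ifelse(concern %in% c("most", "less"), 1L,
         ifelse(concern == "no", 0L, NA_integer_))
}

#' Collapse duplicate records of one compound
#'
#' One record per match key. A compound is toxic if any of its duplicate
#' records is toxic (label = max over duplicates). The representative
#' standardized SMILES is the first by sorted order, so the output is
#' deterministic regardless of input order. The concern category kept is the
#' highest concern present among duplicates (most > less > no > ambiguous >
#' unknown), consistent with the label rule.
#'
#' @param records data.frame with columns \code{key}, \code{std_smiles},
#'   \code{label}, and optionally \code{concern} and \code{source}.
#' @return A deduplicated data.frame, ordered by key.
#' @export
collapse_duplicates <- function(records) {
  stopifnot(is.data.frame(records))
  req <- c("key", "std_smiles", "label")
  if (!all(req %in% names(records))) {
    stop("records must have columns: ", paste(req, collapse = ", "))
  }
  if (any(is.na(records$key) | !nzchar(records$key))) {
    stop("records with missing keys cannot be collapsed")
  }
  concern_rank <- c(most = 1L, less = 2L, no = 3L, ambiguous = 4L, unknown = 5L)
  out <- lapply(split(records, records$key), function(g) {
    r <- g[order(g$std_smiles), , drop = FALSE][1L, , drop = FALSE]
    labs <- g$label[!is.na(g$label)]
    r$label <- if (length(labs)) max(labs) else NA_integer_
    if ("concern" %in% names(g)) {
      r$concern <- g$concern[order(concern_rank[g$concern])][1L]
    }
    if ("source" %in% names(g) && length(unique(g$source)) > 1L) {
      r$source <- "both"
    }
    r
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$key), , drop = FALSE]
}

#' Enrich a concern-ranked dataset with adverse-event-labeled compounds
#'
#' Adds compounds that only appear in the adverse-event dataset (e.g. SIDER
#' cardiac disorders) to the concern-ranked dataset. Compounds present in
#' both always keep the concern-derived label; added compounds get concern
#' category \code{"unknown"}. \code{mode} selects which labels may be added:
#' \code{"toxic_only"} (label 1), \code{"nontoxic_only"} (label 0), or
#' \code{"all"}.
#'
#' @param dictrank deduplicated, keyed data.frame (columns \code{key},
#'   \code{std_smiles}, \code{concern}, \code{label}).
#' @param sider deduplicated, keyed data.frame with binary \code{label}.
#' @param mode one of \code{"toxic_only"}, \code{"nontoxic_only"},
#'   \code{"all"}.
#' @return The enriched dataset with a \code{source} column in
#'   \code{c("DICTrank", "SIDER", "both")}.
#' @export
enrich_with_sider <- function(dictrank, sider,
                              mode = c("toxic_only", "nontoxic_only", "all")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(dictrank), is.data.frame(sider))
  base <- dictrank
  if (!"concern" %in% names(base)) base$concern <- "unknown"
  base$source <- ifelse(base$key %in% sider$key, "both", "DICTrank")
  extra <- sider[!(sider$key %in% dictrank$key), , drop = FALSE]
  keep <- switch(mode,
                 toxic_only = extra$label %in% 1L,
                 nontoxic_only = extra$label %in% 0L,
                 all = !is.na(extra$label))
  extra <- extra[keep, , drop = FALSE]
  if (nrow(extra)) {
    extra <- data.frame(key = extra$key, std_smiles = extra$std_smiles,
                        concern = "unknown", label = extra$label,
                        source = "SIDER", stringsAsFactors = FALSE)
  } else {
    extra <- base[0, c("key", "std_smiles", "concern", "label", "source")]
  }
  out <- rbind(base[, c("key", "std_smiles", "concern", "label", "source")], extra)
  rownames(out) <- NULL
  out[order(out$key), , drop = FALSE]
}

#' Label concordance between two keyed binary datasets
#'
#' Restricts both datasets to their shared keys and reports percent agreement
#' and the F1 score of the second dataset's labels treated as predictions of
#' the first dataset's labels (the truth).
#'
#' @param dictrank keyed data.frame with binary \code{label} (truth).
#' @param sider keyed data.frame with binary \code{label} (prediction).
#' @return A list with \code{n_overlap}, \code{percent_concordant},
#'   \code{f1_of_sider_vs_dictrank}, and the 2x2 \code{confusion} matrix
#'   (truth in rows, prediction in columns).
#' @export
concordance <- function(dictrank, sider) {
  stopifnot(is.data.frame(dictrank), is.data.frame(sider))
  a <- dictrank[!is.na(dictrank$label), c("key", "label")]
  b <- sider[!is.na(sider$label), c("key", "label")]
  shared <- intersect(a$key, b$key)
  conf <- matrix(0L, 2, 2, dimnames = list(truth = c("0", "1"), pred = c("0", "1")))
  if (length(shared) == 0L) {
    return(list(n_overlap = 0L, percent_concordant = NA_real_,
                f1_of_sider_vs_dictrank = NA_real_, confusion = conf))
  }
  truth <- a$label[match(shared, a$key)]
  pred <- b$label[match(shared, b$key)]
  for (t in 0:1) for (p in 0:1) {
    conf[t + 1L, p + 1L] <- sum(truth == t & pred == p)
  }
  tp <- conf["1", "1"]; fp <- conf["0", "1"]; fn <- conf["1", "0"]
  f1 <- if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  list(n_overlap = length(shared),
       percent_concordant = 100 * sum(truth == pred) / length(shared),
       f1_of_sider_vs_dictrank = f1,
       confusion = conf)
}
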