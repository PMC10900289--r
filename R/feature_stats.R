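#' Chi-squared association between a categorical feature and groups
#'
#' Pearson chi-squared on the observed r x c contingency table with no
#' continuity correction; degrees of freedom (r-1)(c-1). Missing values are
#' dropped pairwise before tabulation.
#'
#' @param feature_values categorical (or binary) vector.
#' @param groups categorical grouping vector of equal length.
#' @param feature_name label carried into the result.
#' @param m_comparisons Bonferroni multiplier for the adjusted p-value.
#' @param grouping reported grouping scheme.
#' @return one-row data.frame: \code{feature_name, test, statistic, p_value,
#'   p_adjusted, grouping}.
#' @export
chi_squared_assoc <- function(feature_values, groups, feature_name = "feature",
                              m_comparisons = 1L, grouping = "three_concern") {
  if (length(feature_values) != length(groups)) stop("length mismatch")
  keep <- !is.na(feature_values) & !is.na(groups)
  tab <- table(factor(feature_values[keep]), factor(groups[keep]))
  if (any(rowSums(tab) == 0) || nrow(tab) < 2L) {
    stop("degenerate margin: feature levels ",
         paste(rownames(tab)[rowSums(tab) == 0], collapse = ", "),
         " have no observations (need >= 2 populated levels)")
  }
  if (any(colSums(tab) == 0) || ncol(tab) < 2L) {
    stop("degenerate margin: group levels ",
         paste(colnames(tab)[colSums(tab) == 0], collapse = ", "),
         " have no observations (need >= 2 populated groups)")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  assoc_row(feature_name, "chi_squared", unname(ht$statistic),
            unname(ht$p.value), m_comparisons, grouping)
}

#' Kruskal-Wallis association between a continuous feature and 3+ groups
#'
#' Rank-based H statistic with tie correction and asymptotic chi-squared
#' p-value. For two groups the caller is directed to the Mann-Whitney test.
#'
#' @param feature_values numeric vector.
#' @param groups categorical vector with at least 3 populated levels.
#' @inheritParams chi_squared_assoc
#' @export
kruskal_wallis_assoc <- function(feature_values, groups,
                                 feature_name = "feature", m_comparisons = 1L,
                                 grouping = "three_concern") {
  if (length(feature_values) != length(groups)) stop("length mismatch")
  keep <- is.finite(feature_values) & !is.na(groups)
  g <- droplevels(factor(groups[keep]))
  if (nlevels(g) < 3L) {
    stop("fewer than 3 groups; use mann_whitney_assoc for two-group contrasts")
  }
  x <- feature_values[keep]
  if (length(unique(x)) == 1L) {
    return(assoc_row(feature_name, "kruskal_wallis", 0, 1, m_comparisons, grouping))
  }
  ht <- stats::kruskal.test(x, g)
  assoc_row(feature_name, "kruskal_wallis", unname(ht$statistic),
            unname(ht$p.value), m_comparisons, grouping)
}

#' Mann-Whitney U association between a continuous feature and two groups
#'
#' Two-sided U test. Exact enumeration when both samples have at most 8
#' observations and no ties; mid-rank normal approximation otherwise.
#' Bonferroni adjustment over \code{m_comparisons} pairwise contrasts.
#'
#' @param a,b numeric samples for the two groups.
#' @inheritParams chi_squared_assoc
#' @export
mann_whitney_assoc <- function(a, b, feature_name = "feature",
                               m_comparisons = 1L, grouping = "pairwise") {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) == 0L || length(b) == 0L) stop("empty sample")
  exact <- length(a) <= 8L && length(b) <= 8L && !anyDuplicated(c(a, b))
  ht <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided",
                                            exact = exact, correct = !exact))
  assoc_row(feature_name, "mann_whitney", unname(ht$statistic),
            unname(ht$p.value), m_comparisons, grouping)
}

assoc_row <- function(feature_name, test, statistic, p_value, m, grouping) {
  data.frame(feature_name = feature_name, test = test, statistic = statistic,
             p_value = p_value, p_adjusted = min(1, m * p_value),
             grouping = grouping, stringsAsFactors = FALSE)
}

#' Rank the features of a feature space by association with toxicity labels
#'
#' For every feature column the test follows the column's type: columns with
#' at most two distinct finite values take the chi-squared path; continuous
#' columns take Kruskal-Wallis under the \code{three_concern} scheme, the
#' two-sided Mann-Whitney U test under \code{binary_label}, or the
#' most-vs-no Mann-Whitney contrast (Bonferroni m = 3 for the three pairwise
#' concern contrasts) under \code{pairwise}. Constant features are skipped
#' with a message. Results are ordered by ascending p-value, ties broken by
#' feature name. Feature-wise multiplicity is reported via
#' \code{p_adjusted}, not corrected across features.
#'
#' @param fm feature matrix (rows keyed by compound).
#' @param labels data.frame with \code{key}, \code{concern}, \code{label}.
#' @param scheme \code{"three_concern"}, \code{"binary_label"} or
#'   \code{"pairwise"}.
#' @return data.frame of association results, one row per tested feature.
#' @export
rank_features <- function(fm, labels,
                          scheme = c("three_concern", "binary_label", "pairwise")) {
  scheme <- match.arg(scheme)
  stopifnot(is.matrix(fm), is.data.frame(labels), "key" %in% names(labels))
  keys <- intersect(rownames(fm), labels$key)
  if (length(keys) == 0L) stop("no overlapping keys between features and labels")
  fm <- fm[keys, , drop = FALSE]
  lab <- labels[match(keys, labels$key), ]
  groups <- switch(scheme,
    three_concern = {
      g <- lab$concern
      g[!g %in% c("most", "less", "no")] <- NA
      factor(g, levels = c("most", "less", "no"))
    },
    binary_label = factor(lab$label),
    pairwise = {
      g <- lab$concern
      g[!g %in% c("most", "no")] <- NA
      factor(g, levels = c("most", "no"))
    })
  m_comp <- if (scheme == "pairwise") 3L else 1L
  res <- lapply(colnames(fm), function(fn) {
    x <- fm[, fn]
    ok <- is.finite(x) & !is.na(groups)
    vals <- unique(x[ok])
    if (length(vals) <= 1L) {
      message("skipping constant feature: ", fn)
      return(NULL)
    }
    out <- tryCatch({
      if (length(vals) <= 2L) {
        chi_squared_assoc(x, as.character(groups), feature_name = fn,
                          m_comparisons = m_comp, grouping = scheme)
      } else if (scheme == "three_concern") {
        kruskal_wallis_assoc(x, as.character(groups), feature_name = fn,
                             m_comparisons = m_comp, grouping = scheme)
      } else {
        lv <- levels(groups)
        mann_whitney_assoc(x[ok & groups == lv[1]], x[ok & groups == lv[2]],
                           feature_name = fn, m_comparisons = m_comp,
                           grouping = scheme)
      }
    }, error = function(e) {
      message("skipping feature ", fn, ": ", conditionMessage(e))
      NULL
    })
    out
  })
  res <- do.call(rbind, res)
  if (is.null(res)) stop("no testable features")
  res[order(res$p_value, res$feature_name), , drop = FALSE]
}
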