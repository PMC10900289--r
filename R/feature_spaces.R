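#' Construct a feature matrix
#'
#' Feature matrices are plain numeric matrices with compound keys as row
#' names, feature names as column names, and a \code{space_tag} attribute
#' identifying the feature space. This constructor validates the contract:
#' no duplicate keys or feature names, and (for the \code{structure} space)
#' exactly 2048 binary columns.
#'
#' @param values numeric matrix.
#' @param keys compound identifiers, one per row.
#' @param feature_names one per column.
#' @param space_tag one of \code{structure}, \code{physchem}, \code{moa},
#'   \code{targets}, \code{cmax_total}, \code{cmax_unbound},
#'   \code{omics_morphology}, \code{omics_expression}, \code{omics_ontology},
#'   \code{composite}.
#' @return The validated matrix with \code{space_tag} attribute.
#' @export
feature_matrix <- function(values, keys = rownames(values),
                           feature_names = colnames(values), space_tag) {
  tags <- c("structure", "physchem", "moa", "targets", "cmax_total",
            "cmax_unbound", "omics_morphology", "omics_expression",
            "omics_ontology", "composite")
  stopifnot(is.matrix(values), is.numeric(values), space_tag %in% tags)
  if (is.null(keys) || is.null(feature_names)) {
    stop("feature matrix needs row keys and feature names")
  }
  if (length(keys) != nrow(values) || length(feature_names) != ncol(values)) {
    stop("keys/feature_names do not match matrix dimensions")
  }
  if (anyDuplicated(keys)) stop("duplicate keys in feature matrix")
  if (anyDuplicated(feature_names)) stop("duplicate feature names")
  if (space_tag == "structure") {
    if (ncol(values) != 2048L || !all(values %in% c(0, 1))) {
      stop("structure space must be 2048 binary columns")
    }
  }
  dimnames(values) <- list(keys, feature_names)
  attr(values, "space_tag") <- space_tag
  values
}

#' Morgan-style circular fingerprints (ECFP4, 2048 bits)
#'
#' Computes extended-connectivity fingerprints of radius 2 with Open Babel
#' and folds them to 2048 bits (bitwise OR of the two 2048-bit halves of the
#' native 4096-bit vector). Deterministic: the same molecule always yields
#' the same bit vector, whatever SMILES spelling it arrives in.
#'
#' @param std_smiles character vector of valid standardized SMILES.
#' @param keys optional row identifiers (default: the SMILES themselves).
#' @return A binary matrix with one 2048-column row per compound
#'   (\code{space_tag = "structure"}).
#' @export
structural_fingerprint <- function(std_smiles, keys = std_smiles) {
  stopifnot(is.character(std_smiles), length(std_smiles) > 0L)
  fp <- ob_fpt_matrix(std_smiles, "ECFP4", 4096L)
  folded <- pmin(fp[, 1:2048, drop = FALSE] + fp[, 2049:4096, drop = FALSE], 1)
  feature_matrix(folded, keys = keys,
                 feature_names = paste0("bit_", seq_len(2048L)),
                 space_tag = "structure")
}

#' Tanimoto similarity of two binary vectors
#'
#' \eqn{|a \wedge b| / |a \vee b|}; defined as 0 when both vectors are
#' all-zero.
#'
#' @param a,b binary vectors of equal length.
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprint length mismatch")
  inter <- sum(a > 0 & b > 0)
  union <- sum(a > 0 | b > 0)
  if (union == 0) 0 else inter / union
}

# All-pairs Tanimoto between the rows of two binary matrices, via bit-count
# algebra: |a&b| = a.b, |a|b| = |a|+|b|-a.b. Rows of the result index A.
tanimoto_matrix <- function(A, B) {
  stopifnot(ncol(A) == ncol(B))
  A <- (A > 0) * 1; B <- (B > 0) * 1
  inter <- A %*% t(B)
  union <- outer(rowSums(A), rowSums(B), "+") - inter
  out <- ifelse(union == 0, 0, inter / union)
  dimnames(out) <- list(rownames(A), rownames(B))
  out
}

#' 2-D physicochemical descriptors
#'
#' Computes a 2-D descriptor panel from Open Babel properties (molecular
#' weight, logP, molar refractivity, TPSA, hydrogen-bond donor/acceptor
#' counts) plus SMARTS-derived counts (atoms, bonds, rings, aromatic atoms,
#' rotatable bonds, heteroatoms, halogens, charges, ...). No 3-D descriptors
#' are computed. Raw values may be non-finite for exotic inputs; the
#' dataset-wide drop/clip policy is applied by [clean_descriptor_matrix()].
#'
#' @param std_smiles character vector of valid standardized SMILES.
#' @param keys optional row identifiers.
#' @param set \code{"modeling"} or \code{"interpretable"}; both expose the
#'   same panel here (one descriptor engine backs both views).
#' @return A numeric matrix with \code{space_tag = "physchem"}.
#' @export
physchem_descriptors <- function(std_smiles, keys = std_smiles,
                                 set = c("modeling", "interpretable")) {
  set <- match.arg(set)
  stopifnot(is.character(std_smiles), length(std_smiles) > 0L)
  mols <- ob_parse(std_smiles)
  props <- ChemmineOB::prop_OB(mols)
  smarts_counts <- c(
    n_atoms = "[*]", n_bonds = "*~*", n_arom_atoms = "[a]",
    n_heteroatoms = "[!#6;!#1]", n_halogens = "[F,Cl,Br,I]",
    n_rot_bonds = "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]",
    n_nitrogen = "[#7]", n_oxygen = "[#8]", n_sulfur = "[#16]",
    n_sp3_carbon = "[CX4]", n_double_bonds = "*=*",
    n_pos_charge = "[+,+2,+3]", n_neg_charge = "[-,-2,-3]",
    n_carbonyl = "[CX3]=[OX1]", n_ring_atoms = "[R]"
  )
  counts <- vapply(smarts_counts, function(p) {
    as.numeric(ChemmineOB::smartsSearch_OB(mols, p, uniqueMatches = TRUE))
  }, numeric(length(std_smiles)))
  if (length(std_smiles) == 1L) counts <- matrix(counts, nrow = 1,
                                                 dimnames = list(NULL, names(smarts_counts)))
  n_rings <- counts[, "n_bonds"] - counts[, "n_atoms"] + 1  # single fragment
  m <- cbind(
    mol_weight = props$MW, logp = props$logP, molar_refractivity = props$MR,
    tpsa = props$TPSA, hba = props$HBA1, hbd = props$HBD,
    counts,
    n_rings = n_rings,
    frac_aromatic = ifelse(counts[, "n_atoms"] > 0,
                           counts[, "n_arom_atoms"] / counts[, "n_atoms"], 0)
  )
  feature_matrix(as.matrix(m), keys = keys, feature_names = colnames(m),
                 space_tag = "physchem")
}

#' Dataset-wide descriptor cleanup
#'
#' Columns that fail to compute (non-finite) on every compound are dropped;
#' any residual non-finite entries are clipped to the column's finite
#' extremes (\code{-Inf}/\code{NaN} to the minimum, \code{+Inf} to the
#' maximum), so the returned matrix is entirely finite.
#'
#' @param m numeric matrix (descriptor rows per compound).
#' @param drop_any if TRUE (default), drop a column when it is non-finite for
#'   any compound, mirroring the policy used for the modeling descriptor set;
#'   clipping then only applies when a column would otherwise be empty.
#' @return The cleaned matrix; dropped column names in attribute
#'   \code{"dropped"}.
#' @export
clean_descriptor_matrix <- function(m, drop_any = TRUE) {
  stopifnot(is.matrix(m))
  finite <- is.finite(m)
  drop <- if (drop_any) colSums(!finite) > 0 else colSums(finite) == 0
  kept <- m[, !drop, drop = FALSE]
  fin <- is.finite(kept)
  if (!all(fin)) {
    for (j in which(colSums(!fin) > 0)) {
      col <- kept[, j]
      lo <- min(col[is.finite(col)]); hi <- max(col[is.finite(col)])
      col[is.nan(col) | col == -Inf | is.na(col)] <- lo
      col[col == Inf] <- hi
      kept[, j] <- col
    }
  }
  attr(kept, "dropped") <- colnames(m)[drop]
  attr(kept, "space_tag") <- attr(m, "space_tag")
  kept
}

#' One-hot encode annotation sets
#'
#' Binary presence/absence matrix over the sorted annotation vocabulary;
#' absence of evidence is encoded as 0.
#'
#' @param records named list: compound key -> character vector of annotation
#'   terms (possibly empty).
#' @param space_tag feature-space tag for the result (default \code{"moa"}).
#' @return binary feature matrix, columns in sorted vocabulary order.
#' @export
onehot_annotations <- function(records, space_tag = "moa") {
  stopifnot(is.list(records), !is.null(names(records)))
  vocab <- sort(unique(unlist(records, use.names = FALSE)))
  m <- matrix(0, nrow = length(records), ncol = length(vocab),
              dimnames = list(names(records), vocab))
  for (i in seq_along(records)) {
    m[i, intersect(records[[i]], vocab)] <- 1
  }
  if (length(vocab) == 0L) m <- matrix(0, length(records), 0,
                                       dimnames = list(names(records), NULL))
  feature_matrix(m, keys = names(records),
                 feature_names = colnames(m), space_tag = space_tag)
}

#' Remove low-variance features
#'
#' Keeps columns whose population variance exceeds \code{threshold}. For a
#' binary column with positive fraction p the population variance is
#' p(1 - p), so e.g. a single positive among 2000 compounds
#' (variance ~ 0.0005) falls below the default threshold and is removed.
#'
#' @param m numeric feature matrix.
#' @param threshold variance threshold (default 0.001).
#' @return the filtered matrix (attributes preserved).
#' @export
variance_filter <- function(m, threshold = 0.001) {
  stopifnot(is.matrix(m))
  if (nrow(m) == 0L || ncol(m) == 0L) stop("empty feature matrix")
  n <- nrow(m)
  pop_var <- apply(m, 2, function(x) mean((x - mean(x))^2))
  out <- m[, pop_var > threshold, drop = FALSE]
  attr(out, "space_tag") <- attr(m, "space_tag")
  out
}

#' Aggregate replicate profiles to one profile per compound
#'
#' Elementwise median over the replicate profiles of each compound.
#'
#' @param replicates data.frame whose first column \code{key} identifies the
#'   compound and whose remaining columns are numeric features, one row per
#'   replicate; or a named list of numeric matrices sharing one feature
#'   schema.
#' @param space_tag feature-space tag for the result.
#' @return feature matrix with one row per distinct key.
#' @export
aggregate_profiles <- function(replicates, space_tag = "omics_morphology") {
  if (is.list(replicates) && !is.data.frame(replicates)) {
    schemas <- lapply(replicates, colnames)
    if (length(unique(vapply(schemas, paste, "", collapse = "\r"))) > 1L) {
      stop("replicate profiles do not share one feature schema")
    }
    rows <- lapply(replicates, function(p) apply(p, 2, stats::median))
    m <- do.call(rbind, rows)
    rownames(m) <- names(replicates)
    return(feature_matrix(m, space_tag = space_tag))
  }
  stopifnot(is.data.frame(replicates), names(replicates)[1] == "key")
  feats <- as.matrix(replicates[, -1, drop = FALSE])
  keys <- sort(unique(replicates$key))
  m <- t(vapply(keys, function(k) {
    apply(feats[replicates$key == k, , drop = FALSE], 2, stats::median)
  }, numeric(ncol(feats))))
  if (ncol(feats) == 1L) m <- matrix(m, ncol = 1, dimnames = list(keys, colnames(feats)))
  rownames(m) <- keys
  feature_matrix(m, space_tag = space_tag)
}

#' Similarity-conditional (v-NN) profile imputation
#'
#' For a query compound without its own profile, returns the elementwise
#' median profile over all library compounds whose Tanimoto similarity to the
#' query strictly exceeds \code{sim_threshold} and whose key is not excluded
#' (held-out test compounds must never lend their profiles). The neighbor
#' count v varies per query — this is the v-NN rule, not a fixed k. A query
#' that has its own profile is returned verbatim; a query with no qualifying
#' neighbor is dropped (returns \code{NULL}).
#'
#' @param query_key compound identifier.
#' @param fingerprints binary feature matrix (structure space) containing the
#'   query and the library compounds.
#' @param profiles feature matrix of available profiles (rows = keys that
#'   have a measured profile).
#' @param sim_threshold strict similarity threshold (default 0.70).
#' @param excluded_keys keys barred from the neighbor pool.
#' @return numeric profile vector, or \code{NULL} if the compound is dropped.
#' @export
vnn_impute <- function(query_key, fingerprints, profiles,
                       sim_threshold = 0.70, excluded_keys = character()) {
  if (!query_key %in% rownames(fingerprints)) {
    stop("no fingerprint for query ", query_key)
  }
  if (query_key %in% rownames(profiles)) {
    return(profiles[query_key, ])
  }
  pool <- setdiff(intersect(rownames(profiles), rownames(fingerprints)),
                  c(excluded_keys, query_key))
  if (length(pool) == 0L) return(NULL)
  sims <- tanimoto_matrix(fingerprints[query_key, , drop = FALSE],
                          fingerprints[pool, , drop = FALSE])[1, ]
  nbr <- pool[sims > sim_threshold]
  if (length(nbr) == 0L) return(NULL)
  apply(profiles[nbr, , drop = FALSE], 2, stats::median)
}

#' Impute or drop a set of compounds against a profile library
#'
#' Batch driver for [vnn_impute()]: returns a completed profile matrix over
#' the queries that have (or could borrow) a profile, and the keys that were
#' dropped.
#'
#' @inheritParams vnn_impute
#' @param query_keys identifiers to complete.
#' @return list with \code{profiles} (feature matrix) and \code{dropped}
#'   (character vector of keys with no profile and no qualifying neighbor).
#' @export
vnn_impute_all <- function(query_keys, fingerprints, profiles,
                           sim_threshold = 0.70, excluded_keys = character()) {
  res <- lapply(query_keys, vnn_impute, fingerprints = fingerprints,
                profiles = profiles, sim_threshold = sim_threshold,
                excluded_keys = excluded_keys)
  got <- !vapply(res, is.null, logical(1))
  m <- do.call(rbind, res[got])
  if (!is.null(m)) rownames(m) <- query_keys[got]
  list(profiles = m, dropped = query_keys[!got])
}

#' Attach log-scale Cmax as a model feature column
#'
#' Peak plasma concentrations span orders of magnitude, so the modeling
#' feature is log10(Cmax in micromolar).
#'
#' @param cmax data.frame with columns \code{key}, \code{cmax_total} and
#'   optionally \code{cmax_unbound} (micromolar).
#' @param which \code{"total"} or \code{"unbound"}.
#' @return single-column feature matrix over the keys with a value.
#' @export
cmax_feature <- function(cmax, which = c("total", "unbound")) {
  which <- match.arg(which)
  col <- paste0("cmax_", which)
  stopifnot(is.data.frame(cmax), "key" %in% names(cmax), col %in% names(cmax))
  v <- cmax[[col]]
  keep <- !is.na(v) & v > 0
  m <- matrix(log10(v[keep]), ncol = 1,
              dimnames = list(cmax$key[keep], paste0("log10_", col)))
  feature_matrix(m, space_tag = paste0("cmax_", which))
}
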