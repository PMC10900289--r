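# Fragment vocabulary for the synthetic-compound assembler. Blocks are
# chemically valid SMILES pieces that concatenate into valid molecules (each
# block opens and closes its own rings, begins and ends on an atom).
# The planted toxicophore (thiophene) uses the only aromatic sulfur in the
# vocabulary, so it cannot arise by accident from other blocks.
.internal_blocks <- c(
  "C", "CC", "CCC", "CC(C)", "C(C)C", "CCCC",
  "CO", "CCO", "COC", "CCOC", "OC",
  "CN", "CCN", "CNC", "CN(C)C",
  "C=C", "CC=C", "C=CC",
  "CC(=O)", "C(=O)", "C(=O)O", "C(=O)N",
  "CSC", "CS",
  "c1ccccc1", "Cc1ccccc1", "c1ccc(C)cc1",
  "C(F)", "C(Cl)", "CC(F)"
)
.terminal_blocks <- c(
  "C", "O", "N", "Cl", "F", "Br", "CO", "CN", "C#N",
  "C(F)(F)F", "C(=O)O", "C(=O)N", "N(C)C", "[N+](=O)[O-]",
  "S(=O)(=O)N", "c1ccccc1", "c1ccco1", "c1ccncc1", "C1CC1", "C1CCCC1"
)
.default_toxicophore <- "c1cccs1"

#' Configuration of a synthetic cardiotoxicity study
#'
#' Defines the conditions a synthetic study emulates: a three-category
#' concern label with the 299:443:278 most:less:no balance, a planted
#' toxicophore substructure that drives toxicity up to a label-noise rate,
#' class-shifted lognormal Cmax, sparse multi-label annotations with
#' mechanism-term enrichment among toxic compounds, and Gaussian omics
#' profiles with a mean shift on the informative features and a missing
#' fraction to exercise v-NN imputation.
#'
#' @param n_compounds total compounds (default 1020).
#' @param concern_proportions probabilities of most/less/no concern (must
#'   sum to 1; default proportional to 299:443:278).
#' @param toxicophore_smarts planted substructure (default thiophene).
#' @param label_noise probability that a toxic compound lacks (or a
#'   nontoxic compound carries) the toxicophore; in \[0, 0.5).
#' @param cmax_log_mean_toxic,cmax_log_mean_nontoxic,cmax_log_sd log10
#'   micromolar location/scale of the Cmax distributions by class.
#' @param n_annotation_terms size of the annotation vocabulary.
#' @param annotation_enrichment odds multiplier (>= 1) of the designated
#'   mechanism terms among toxic compounds.
#' @param n_omics_features,n_informative omics panel size and number of
#'   label-shifted features.
#' @param omics_effect_size standardized mean shift of informative features
#'   for toxic compounds.
#' @param missing_profile_fraction fraction of compounds with no omics
#'   profile, in \[0, 1).
#' @param seed integer seed.
#' @return validated config list of class \code{synthetic_study_config}.
#' @export
synthetic_study_config <- function(n_compounds = 1020L,
                                   concern_proportions = c(299, 443, 278) / 1020,
                                   toxicophore_smarts = .default_toxicophore,
                                   label_noise = 0.1,
                                   cmax_log_mean_toxic = 0.5,
                                   cmax_log_mean_nontoxic = -0.5,
                                   cmax_log_sd = 1.0,
                                   n_annotation_terms = 30L,
                                   annotation_enrichment = 4,
                                   n_omics_features = 100L,
                                   n_informative = 10L,
                                   omics_effect_size = 1.0,
                                   missing_profile_fraction = 0.15,
                                   seed = 1L) {
  stopifnot(n_compounds >= 10L,
            length(concern_proportions) == 3L,
            abs(sum(concern_proportions) - 1) < 1e-8,
            label_noise >= 0, label_noise < 0.5,
            n_informative <= n_omics_features,
            missing_profile_fraction >= 0, missing_profile_fraction < 1,
            annotation_enrichment >= 1)
  if (is.na(ob_convert(toxicophore_smarts, to = "CAN"))) {
    stop("invalid toxicophore pattern: ", toxicophore_smarts)
  }
  structure(list(n_compounds = as.integer(n_compounds),
                 concern_proportions = concern_proportions,
                 toxicophore_smarts = toxicophore_smarts,
                 label_noise = label_noise,
                 cmax_log_mean_toxic = cmax_log_mean_toxic,
                 cmax_log_mean_nontoxic = cmax_log_mean_nontoxic,
                 cmax_log_sd = cmax_log_sd,
                 n_annotation_terms = as.integer(n_annotation_terms),
                 annotation_enrichment = annotation_enrichment,
                 n_omics_features = as.integer(n_omics_features),
                 n_informative = as.integer(n_informative),
                 omics_effect_size = omics_effect_size,
                 missing_profile_fraction = missing_profile_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_study_config")
}

# Assemble one random molecule: 1-3 internal blocks plus a terminal block
# (the toxicophore when planted). Each block closes its own rings, so plain
# concatenation yields valid SMILES.
assemble_smiles <- function(n, with_toxicophore, toxicophore) {
  vapply(seq_len(n), function(i) {
    k <- sample(1:3, 1L)
    body <- paste(sample(.internal_blocks, k, replace = TRUE), collapse = "")
    tail <- if (with_toxicophore) toxicophore else sample(.terminal_blocks, 1L)
    paste0(body, tail)
  }, character(1))
}

# Unique standardized molecules, with or without the planted toxicophore.
# Regenerates on key collisions; errors if the vocabulary cannot supply
# enough distinct molecules.
generate_unique_pool <- function(n, with_toxicophore, toxicophore) {
  pool <- NULL
  for (round in 1:30) {
    need <- n - NROW(pool)
    if (need <= 0L) break
    raw <- assemble_smiles(need * 2L, with_toxicophore, toxicophore)
    std <- standardize_compounds(raw)
    std <- std[!duplicated(std$std_inchi), , drop = FALSE]
    if (!is.null(pool)) std <- std[!std$std_inchi %in% pool$std_inchi, , drop = FALSE]
    pool <- rbind(pool, std)
  }
  if (NROW(pool) < n) stop("could not generate ", n, " unique compounds")
  pool[seq_len(n), , drop = FALSE]
}

#' Generate the compounds of a synthetic study
#'
#' Draws concern categories from the configured proportions, derives binary
#' labels (most/less toxic, no nontoxic), and assembles unique standardized
#' molecules such that toxic compounds carry the planted toxicophore with
#' probability 1 - label_noise and nontoxic compounds with probability
#' label_noise. Deterministic given the config seed.
#'
#' @param cfg a [synthetic_study_config()].
#' @return data.frame \code{key, raw_smiles, std_smiles, concern, label,
#'   has_toxicophore, source}.
#' @export
generate_compounds <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_study_config"))
  set.seed(cfg$seed)
  concern <- sample(c("most", "less", "no"), cfg$n_compounds, replace = TRUE,
                    prob = cfg$concern_proportions)
  label <- binarize_concern(concern)
  carries <- ifelse(label == 1L,
                    stats::runif(cfg$n_compounds) >= cfg$label_noise,
                    stats::runif(cfg$n_compounds) < cfg$label_noise)
  tox_pool <- generate_unique_pool(sum(carries), TRUE, cfg$toxicophore_smarts)
  non_pool <- generate_unique_pool(sum(!carries), FALSE, cfg$toxicophore_smarts)
  out <- data.frame(key = character(cfg$n_compounds),
                    raw_smiles = character(cfg$n_compounds),
                    std_smiles = character(cfg$n_compounds),
                    concern = concern, label = label,
                    has_toxicophore = carries, source = "synthetic",
                    stringsAsFactors = FALSE)
  out$key[carries] <- tox_pool$std_inchi
  out$raw_smiles[carries] <- tox_pool$raw_smiles
  out$std_smiles[carries] <- tox_pool$std_smiles
  out$key[!carries] <- non_pool$std_inchi
  out$raw_smiles[!carries] <- non_pool$raw_smiles
  out$std_smiles[!carries] <- non_pool$std_smiles
  if (anyDuplicated(out$key)) {
    dup <- duplicated(out$key)
    out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Generate auxiliary data for a synthetic study
#'
#' Cmax values are lognormal with class-dependent log10 means; annotations
#' are sparse Bernoulli sets over a fixed vocabulary with the designated
#' mechanism terms enriched (odds multiplier) among toxic compounds; omics
#' profiles are Gaussian with a mean shift on the informative features for
#' toxic compounds, and a configured fraction of compounds carries no
#' profile at all (the targets for v-NN imputation).
#'
#' @param cfg a [synthetic_study_config()].
#' @param compounds output of [generate_compounds()].
#' @return list: \code{cmax} (data.frame \code{key, cmax_total,
#'   cmax_unbound}), \code{annotations} (named list of term vectors),
#'   \code{omics} (feature matrix over profiled compounds),
#'   \code{missing_keys}, \code{informative_features},
#'   \code{mechanism_terms}.
#' @export
generate_auxiliary <- function(cfg, compounds) {
  stopifnot(inherits(cfg, "synthetic_study_config"), is.data.frame(compounds))
  set.seed(cfg$seed + 7919L)
  n <- nrow(compounds)
  toxic <- compounds$label == 1L
  log_mu <- ifelse(toxic, cfg$cmax_log_mean_toxic, cfg$cmax_log_mean_nontoxic)
  cmax_total <- 10^stats::rnorm(n, log_mu, cfg$cmax_log_sd)
  fu <- stats::rbeta(n, 2, 2)  # free fraction in (0,1)
  cmax <- data.frame(key = compounds$key, cmax_total = cmax_total,
                     cmax_unbound = cmax_total * fu, stringsAsFactors = FALSE)

  terms <- sprintf("term_%02d", seq_len(cfg$n_annotation_terms))
  n_mech <- min(5L, cfg$n_annotation_terms)
  mech <- terms[seq_len(n_mech)]
  p0 <- 0.05
  odds1 <- cfg$annotation_enrichment * p0 / (1 - p0)
  p1 <- odds1 / (1 + odds1)
  annotations <- lapply(seq_len(n), function(i) {
    p <- rep(p0, cfg$n_annotation_terms)
    if (toxic[i]) p[seq_len(n_mech)] <- p1
    terms[stats::runif(cfg$n_annotation_terms) < p]
  })
  names(annotations) <- compounds$key

  feats <- sprintf("omics_%03d", seq_len(cfg$n_omics_features))
  informative <- feats[seq_len(cfg$n_informative)]
  omics <- matrix(stats::rnorm(n * cfg$n_omics_features), nrow = n,
                  dimnames = list(compounds$key, feats))
  omics[toxic, seq_len(cfg$n_informative)] <-
    omics[toxic, seq_len(cfg$n_informative)] + cfg$omics_effect_size
  n_missing <- floor(cfg$missing_profile_fraction * n)
  missing_keys <- if (n_missing > 0L) {
    sample(compounds$key, n_missing)
  } else character(0)
  omics <- omics[!rownames(omics) %in% missing_keys, , drop = FALSE]
  list(cmax = cmax, annotations = annotations,
       omics = feature_matrix(omics, space_tag = "omics_expression"),
       missing_keys = missing_keys,
       informative_features = informative, mechanism_terms = mech)
}
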