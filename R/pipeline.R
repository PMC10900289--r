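#' Assemble a pipeline configuration
#'
#' @param synthetic named list of arguments for [synthetic_study_config()]
#'   (synthetic mode), or NULL when \code{inputs} supplies CSV paths.
#' @param inputs named list of CSV paths (\code{dictrank} with columns
#'   \code{smiles, concern}; \code{sider} with columns \code{smiles, label});
#'   ignored in synthetic mode.
#' @param variant dataset variant: \code{dictrank},
#'   \code{plus_sider_toxic}, \code{plus_sider_nontoxic},
#'   \code{plus_sider_all}.
#' @param spaces feature spaces to model (subset of \code{structure},
#'   \code{physchem}, \code{omics_expression}).
#' @param seed modeling seed.
#' @param test_fraction held-out fraction, stratified by label.
#' @param out_dir output directory for stage tables, or NULL to skip writes.
#' @return validated config list of class \code{dictox_pipeline_config}.
#' @export
pipeline_config <- function(synthetic = list(), inputs = NULL,
                            variant = c("dictrank", "plus_sider_toxic",
                                        "plus_sider_nontoxic", "plus_sider_all"),
                            spaces = c("structure", "omics_expression"),
                            seed = 1L, test_fraction = 90 / 1020,
                            out_dir = NULL) {
  variant <- match.arg(variant)
  stopifnot(all(spaces %in% c("structure", "physchem", "omics_expression")),
            test_fraction > 0, test_fraction < 0.5)
  if (!is.null(inputs)) {
    missing <- unlist(inputs)[!file.exists(unlist(inputs))]
    if (length(missing)) stop("missing input file(s): ", paste(missing, collapse = ", "))
  }
  structure(list(synthetic = synthetic, inputs = inputs, variant = variant,
                 spaces = spaces, seed = as.integer(seed),
                 test_fraction = test_fraction, out_dir = out_dir),
            class = "dictox_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys mirror [pipeline_config()]
#'   arguments.
#' @return a \code{dictox_pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

# Deterministic md5 of an R object via its canonical JSON rendering.
hash_object <- function(obj) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = 12)), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the end-to-end pipeline
#'
#' Executes standardize, assemble, featurize, stats, alerts, train,
#' evaluate, ensemble and ad in order, with one seeded generator per stage.
#' The held-out test split is fixed before any training; test compounds are
#' excluded from v-NN neighbor pools, from alert mining, and from threshold
#' optimization, and the manifest records a leak audit attesting this. Any
#' stage failure aborts with the stage named.
#'
#' @param config a \code{dictox_pipeline_config} (or list coercible to one).
#' @return the run manifest: per-stage record counts, seeds, hashes, leak
#'   audit, and the evaluation reports.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "dictox_pipeline_config")) {
    config <- do.call(pipeline_config, config)
  }
  manifest <- list(seed = config$seed, variant = config$variant,
                   spaces = config$spaces, stages = list())
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    res
  }
  note <- function(name, counts, hash = NULL) {
    manifest$stages[[name]] <<- c(list(n = counts),
                                  if (!is.null(hash)) list(hash = hash))
  }

  # -- standardize ----------------------------------------------------------
  synthetic_mode <- is.null(config$inputs)
  std_data <- run_stage("standardize", {
    if (synthetic_mode) {
      cfg <- do.call(synthetic_study_config,
                     c(config$synthetic, list(seed = config$seed)))
      compounds <- generate_compounds(cfg)
      aux <- generate_auxiliary(cfg, compounds)
      # synthetic adverse-event dataset: overlapping subset with noisy
      # labels plus a few novel compounds, to exercise enrichment
      set.seed(cfg$seed + 104729L)
      overlap <- compounds[sample.int(nrow(compounds), floor(0.6 * nrow(compounds))), ]
      flip <- stats::runif(nrow(overlap)) < 0.1
      sider <- data.frame(key = overlap$key, std_smiles = overlap$std_smiles,
                          label = ifelse(flip, 1L - overlap$label, overlap$label),
                          stringsAsFactors = FALSE)
      extra <- generate_unique_pool(max(10L, floor(0.05 * nrow(compounds))),
                                    FALSE, cfg$toxicophore_smarts)
      extra <- extra[!extra$std_inchi %in% compounds$key, , drop = FALSE]
      sider <- rbind(sider, data.frame(key = extra$std_inchi,
                                       std_smiles = extra$std_smiles,
                                       label = rep_len(c(1L, 0L), nrow(extra))))
      list(cfg = cfg, compounds = compounds, aux = aux, sider = sider)
    } else {
      dict_raw <- utils::read.csv(config$inputs$dictrank, stringsAsFactors = FALSE)
      sid_raw <- utils::read.csv(config$inputs$sider, stringsAsFactors = FALSE)
      if (!"smiles" %in% names(dict_raw) || !"concern" %in% names(dict_raw)) {
        stop("dictrank input needs columns smiles, concern")
      }
      if (!"smiles" %in% names(sid_raw) || !"label" %in% names(sid_raw)) {
        stop("sider input needs columns smiles, label")
      }
      ds <- standardize_compounds(dict_raw$smiles)
      ss <- standardize_compounds(sid_raw$smiles)
      list(cfg = NULL,
           compounds = data.frame(key = ds$std_inchi, raw_smiles = ds$raw_smiles,
                                  std_smiles = ds$std_smiles,
                                  concern = dict_raw$concern,
                                  label = binarize_concern(dict_raw$concern),
                                  stringsAsFactors = FALSE),
           aux = NULL,
           sider = data.frame(key = ss$std_inchi, std_smiles = ss$std_smiles,
                              label = as.integer(sid_raw$label),
                              stringsAsFactors = FALSE))
    }
  })
  note("standardize", nrow(std_data$compounds),
       hash_object(std_data$compounds$key))

  # -- assemble -------------------------------------------------------------
  assembled <- run_stage("assemble", {
    comp <- std_data$compounds
    if (!all(c("key", "std_smiles", "label") %in% names(comp))) {
      stop("schema violation in compound table")
    }
    dict <- collapse_duplicates(comp[!is.na(comp$label), , drop = FALSE])
    sider <- collapse_duplicates(
      cbind(std_data$sider, concern = "unknown"))
    conc <- concordance(dict, sider)
    ds <- switch(config$variant,
                 dictrank = { d <- dict; d$source <- "DICTrank"; d },
                 plus_sider_toxic = enrich_with_sider(dict, sider, "toxic_only"),
                 plus_sider_nontoxic = enrich_with_sider(dict, sider, "nontoxic_only"),
                 plus_sider_all = enrich_with_sider(dict, sider, "all"))
    list(ds = ds, concordance = conc)
  })
  note("assemble", nrow(assembled$ds), hash_object(assembled$ds$key))
  manifest$concordance <- assembled$concordance[c("n_overlap", "percent_concordant",
                                                  "f1_of_sider_vs_dictrank")]

  # fixed, stratified held-out split -- before any training ----------------
  ds <- assembled$ds
  set.seed(config$seed + 2L)
  test_keys <- unlist(lapply(c(0L, 1L), function(cl) {
    k <- ds$key[ds$label == cl]
    sample(k, max(1L, round(config$test_fraction * length(k))))
  }))
  train_keys <- setdiff(ds$key, test_keys)
  manifest$test_keys_hash <- hash_object(sort(test_keys))

  # -- featurize ------------------------------------------------------------
  feats <- run_stage("featurize", {
    fp <- structural_fingerprint(ds$std_smiles, keys = ds$key)
    out <- list(structure = fp)
    if ("physchem" %in% config$spaces) {
      pc <- physchem_descriptors(ds$std_smiles, keys = ds$key)
      out$physchem <- clean_descriptor_matrix(pc)
    }
    if (synthetic_mode && "omics_expression" %in% config$spaces) {
      aux <- std_data$aux
      present <- aux$omics[intersect(rownames(aux$omics), ds$key), , drop = FALSE]
      imput <- vnn_impute_all(setdiff(ds$key, rownames(present)), fp,
                              feature_matrix(present, space_tag = "omics_expression"),
                              sim_threshold = 0.70, excluded_keys = test_keys)
      omics <- rbind(present, imput$profiles)
      out$omics_expression <- feature_matrix(omics, space_tag = "omics_expression")
      out$omics_dropped <- imput$dropped
    }
    out
  })
  note("featurize", nrow(feats$structure))

  # -- stats ----------------------------------------------------------------
  stats_res <- run_stage("stats", {
    if (!is.null(feats$omics_expression)) {
      rank_features(feats$omics_expression, ds, scheme = "three_concern")
    } else {
      rank_features(feats$structure[, seq_len(64L)], ds, scheme = "binary_label")
    }
  })
  note("stats", nrow(stats_res))

  # -- alerts ---------------------------------------------------------------
  alerts <- run_stage("alerts", {
    train_ds <- ds[ds$key %in% train_keys, , drop = FALSE]
    mined <- mine_alerts(train_ds, min_occurrence = 5L,
                         setting = c("all_compounds", "toxic_only"),
                         scheme = "binary_label")
    merged <- filter_and_merge(mined)
    screen <- screen_compounds(ds[ds$key %in% test_keys, c("key", "std_smiles")],
                               merged, exclude_keys = train_keys)
    list(mined = mined, merged = merged, screen = screen)
  })
  note("alerts", nrow(alerts$merged), hash_object(alerts$merged$pattern))

  # -- train ----------------------------------------------------------------
  models <- run_stage("train", {
    train_lab <- ds[ds$key %in% train_keys, c("key", "label")]
    out <- list()
    for (sp in config$spaces) {
      fm <- feats[[sp]]
      if (is.null(fm)) next
      fm_train <- fm[intersect(rownames(fm), train_keys), , drop = FALSE]
      attr(fm_train, "space_tag") <- sp
      out[[sp]] <- cv_train(fm_train, train_lab, seed = config$seed)
    }
    out
  })
  note("train", length(models))

  # -- evaluate -------------------------------------------------------------
  evals <- run_stage("evaluate", {
    lapply(models, function(m) {
      fm <- feats[[m$space_tag]]
      keys <- intersect(test_keys, rownames(fm))
      sc <- model_scores(m, fm, keys)
      y <- ds$label[match(keys, ds$key)]
      evaluate_predictions(sc, y, m$threshold)
    })
  })
  note("evaluate", length(evals))

  # -- ensemble -------------------------------------------------------------
  ens <- run_stage("ensemble", {
    keys <- Reduce(intersect, lapply(models, function(m)
      intersect(test_keys, rownames(feats[[m$space_tag]]))))
    pred <- ensemble_predict(models, feats, keys)
    y <- ds$label[match(keys, ds$key)]
    list(pred = pred, report = evaluate_predictions(pred$score, y, 0.5))
  })
  note("ensemble", nrow(ens$pred))

  # -- ad -------------------------------------------------------------------
  ad <- run_stage("ad", {
    m <- models$structure
    if (is.null(m)) m <- models[[1]]
    keys <- intersect(test_keys, rownames(feats$structure))
    ad_report(keys, m, feats$structure, ds,
              fm = feats[[m$space_tag]])
  })
  note("ad", sum(ad$per_bin$n))

  manifest$leak_audit <- list(
    test_train_overlap = length(intersect(test_keys,
                                          unlist(lapply(models, `[[`, "training_keys")))),
    vnn_excluded_test = TRUE,
    alerts_mined_on_train_only = TRUE)
  manifest$evaluations <- evals
  manifest$ensemble <- ens$report
  manifest$ad <- ad$per_bin
  manifest$hash <- hash_object(manifest[c("stages", "test_keys_hash", "concordance")])

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(ds, file.path(config$out_dir, "dataset.csv"), row.names = FALSE)
    utils::write.csv(alerts$merged, file.path(config$out_dir, "alerts.csv"),
                     row.names = FALSE)
    utils::write.csv(stats_res, file.path(config$out_dir, "feature_stats.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest[c("seed", "variant", "stages", "concordance",
                                    "test_keys_hash", "leak_audit", "hash")],
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = 12, pretty = TRUE)
  }
  manifest
}
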