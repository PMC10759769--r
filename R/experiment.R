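#' Configuration of a full simulate / extract / fuse / train experiment
#'
#' @param dataset A [dataset_config()] (its seed defaults to `seed`).
#' @param feature_sets Subset of `c("enose", "image", "fused")`.
#' @param targets `"region"` (classification) plus any physicochemical
#'   field names (regression). Defaults to region and the ten modelled
#'   quality indices (sugars are generated but not modelled by default).
#' @param n_components Retained principal components (default 4).
#' @param folds Cross-validation folds (default 10).
#' @param seed Master seed; the split, folds and dataset seeds derive
#'   from it.
#' @return A `kiwi_experiment_config` list.
#' @export
experiment_config <- function(dataset = dataset_config(seed = seed),
                              feature_sets = c("enose", "image", "fused"),
                              targets = c("region", "firmness", "ssc", "ta",
                                          "bar", "ph", "vitamin_c", "tp",
                                          "tac", "dpph", "frap"),
                              n_components = 4, folds = 10, seed = 1) {
  feature_sets <- match.arg(feature_sets, c("enose", "image", "fused"),
                            several.ok = TRUE)
  bad <- setdiff(targets, c("region", physchem_fields()))
  if (length(bad)) stop("unknown target(s): ", paste(bad, collapse = ", "))
  if (length(feature_sets) < 1 || length(targets) < 1) {
    stop("need at least one feature set and one target")
  }
  structure(list(dataset = dataset, feature_sets = feature_sets,
                 targets = targets, n_components = as.integer(n_components),
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "kiwi_experiment_config")
}

#' Reduce one sample to its feature payload
#'
#' Extracts the 46 visual features and 13 MSR features of a sample and
#' drops the images, keeping label, physicochemical record and sample id.
#' Suitable as the `transform` of [generate_dataset()] to stream large
#' datasets at full image resolution without exhausting memory.
#'
#' @param sample A `kiwi_sample`.
#' @param crop_size Passed to [extract_image_features()].
#' @return List with `sample_id`, `label`, `physchem`, `image_features`,
#'   `enose_features`.
#' @export
extract_sample_features <- function(sample, crop_size = 1600) {
  list(sample_id = sample$sample_id,
       label = sample$label,
       physchem = sample$physchem,
       image_features = extract_image_features(sample$whole_image,
                                               sample$cut_image,
                                               crop_size = crop_size),
       enose_features = extract_enose_features(sample$enose))
}

# Feature matrices (image, enose, fused) from slim per-sample payloads.
.feature_tables <- function(slim) {
  img <- t(vapply(slim, `[[`, numeric(46), "image_features"))
  nose <- t(vapply(slim, `[[`, numeric(13), "enose_features"))
  fused <- t(vapply(seq_along(slim), function(k) {
    fuse_features(img[k, ], nose[k, ])
  }, numeric(59)))
  rownames(img) <- rownames(nose) <- rownames(fused) <-
    vapply(slim, `[[`, "", "sample_id")
  list(image = img, enose = nose, fused = fused)
}

#' Run the end-to-end experiment
#'
#' Simulates the dataset, extracts visual and e-nose features, splits
#' two-thirds / one-third stratified by region, and for every requested
#' feature set fits a calibration PCA followed by grid-searched SVM
#' (region classification) and SVR (physicochemical regression) models
#' with per-stage reports. Deterministic given the config.
#'
#' @param config A [kiwi_experiment_config][experiment_config()].
#' @param samples Optional pre-generated dataset (must match
#'   `config$dataset`); generated when NULL.
#' @param out Optional directory; when given, the report is written there
#'   via [write_report()].
#' @param quiet Suppress per-stage progress messages (default TRUE).
#' @return A `kiwi_experiment_report` list: `results` (tidy data frame:
#'   feature_set, target, stage, rmse, accuracy, r_squared, cost, gamma),
#'   `msr_summary`, `explained_variance` (per feature set), `fits`
#'   (nested `kiwi_svm_fit` objects), `split`, and `config`.
#' @export
run_experiment <- function(config, samples = NULL, out = NULL, quiet = TRUE) {
  stopifnot(inherits(config, "kiwi_experiment_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  if (is.null(samples)) {
    say("simulating and reducing %d samples", 3 * config$dataset$n_per_region)
    slim <- generate_dataset(config$dataset, transform = extract_sample_features)
  } else {
    say("extracting features from %d pre-generated samples", length(samples))
    slim <- lapply(samples, extract_sample_features)
  }
  labels <- dataset_labels(slim)
  feats <- .feature_tables(slim)
  physchem <- t(vapply(slim, function(s) s$physchem,
                       numeric(length(physchem_fields()))))
  msr <- region_msr_summary(labels, feats$enose)
  split <- split_dataset(labels, seed = config$seed + 1L)
  cal <- split$calibration; tst <- split$test

  results <- list()
  fits <- list()
  expl <- list()
  for (fs in config$feature_sets) {
    say("feature set '%s': PCA + grid search", fs)
    x <- feats[[fs]]
    pca <- fit_pca(x[cal, , drop = FALSE], n_components = config$n_components)
    expl[[fs]] <- pca$explained_variance
    s_cal <- predict(pca, x[cal, , drop = FALSE])
    s_tst <- predict(pca, x[tst, , drop = FALSE])
    fits[[fs]] <- list(pca = pca)
    for (tg in config$targets) {
      fit <- if (tg == "region") {
        grid_search_svm(s_cal, labels[cal], s_tst, labels[tst],
                        folds = config$folds, seed = config$seed + 2L)
      } else {
        grid_search_svr(s_cal, physchem[cal, tg], s_tst, physchem[tst, tg],
                        folds = config$folds, seed = config$seed + 2L)
      }
      fits[[fs]][[tg]] <- fit
      rr <- fit$reports
      rr <- cbind(feature_set = fs, target = tg, rr)
      results[[paste(fs, tg)]] <- rr
    }
  }
  report <- structure(list(
    results = do.call(rbind, c(results, make.row.names = FALSE)),
    msr_summary = msr,
    explained_variance = expl,
    fits = fits,
    split = split,
    n_samples = length(slim),
    config = config,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "kiwi_experiment_report")
  if (!is.null(out)) write_report(report, out)
  report
}

#' Rank feature sets per target
#'
#' Orders the feature sets of a report by their validation metric
#' (accuracy for region classification, R-squared for regression),
#' descending. Ties keep the canonical order enose < image < fused.
#'
#' @param report A `kiwi_experiment_report`.
#' @return Data frame with `target`, `feature_set`, `metric`, `rank`.
#' @export
compare_feature_sets <- function(report) {
  stopifnot(inherits(report, "kiwi_experiment_report"))
  res <- report$results[report$results$stage == "validation", ]
  out <- lapply(unique(res$target), function(tg) {
    d <- res[res$target == tg, ]
    if (nrow(d) == 0) stop("no entries for target ", tg)
    if (nrow(d) < 2) stop("need >= 2 feature sets for target ", tg)
    metric <- if (tg == "region") d$accuracy else d$r_squared
    canon <- match(d$feature_set, c("enose", "image", "fused"))
    ord <- order(-metric, canon)
    data.frame(target = tg, feature_set = d$feature_set[ord],
               metric = metric[ord], rank = seq_along(ord))
  })
  do.call(rbind, out)
}

#' Write an experiment report to disk
#'
#' Emits `report.json` (metrics, chosen hyperparameters, explained
#' variance, MSR summary) and per-table CSVs under `tables/`: the region
#' classification table and one regression table per feature set, plus
#' the per-region MSR means.
#'
#' @param report A `kiwi_experiment_report`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(file.path(dir, "tables"), recursive = TRUE, showWarnings = FALSE)
  payload <- list(
    results = report$results,
    explained_variance = report$explained_variance,
    msr_summary = report$msr_summary,
    n_samples = report$n_samples,
    feature_sets = report$config$feature_sets,
    targets = report$config$targets,
    seed = report$config$seed
  )
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  res <- report$results
  cls <- res[res$target == "region", ]
  if (nrow(cls)) {
    write.csv(cls, file.path(dir, "tables", "classification.csv"),
              row.names = FALSE)
  }
  for (fs in unique(res$feature_set)) {
    reg <- res[res$feature_set == fs & res$target != "region", ]
    if (nrow(reg)) {
      write.csv(reg, file.path(dir, "tables", paste0("regression_", fs, ".csv")),
                row.names = FALSE)
    }
  }
  write.csv(report$msr_summary, file.path(dir, "tables", "msr_summary.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' @export
print.kiwi_experiment_report <- function(x, ...) {
  cat(sprintf("<kiwi_experiment_report> %d samples, %d feature set(s), %d target(s), %.1f s\n",
              x$n_samples, length(x$config$feature_sets),
              length(x$config$targets), x$elapsed_s))
  print(x$results, row.names = FALSE)
  invisible(x)
}
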