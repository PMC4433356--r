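#' Classification scheme specifications
#'
#' The four input datasets compared by the pipeline:
#' scheme 1 `HMS` — the 4-band pansharpened reflectance stack;
#' scheme 2 `HMS5VI` — the 5 vegetation-index bands;
#' scheme 3 `SpecTex` — the 4 Lee-sigma texture bands;
#' scheme 4 `HMS13B` — all 13 bands stacked `[HMS, HMS5VI, SpecTex]`.
#'
#' @param scheme_id integer 1..4 or a dataset name.
#' @return list of class `scheme_spec` with `scheme_id`, `dataset_name`,
#'   `n_bands`.
#' @export
scheme_spec <- function(scheme_id) {
  names <- c("HMS", "HMS5VI", "SpecTex", "HMS13B")
  bands <- c(4L, 5L, 4L, 13L)
  if (is.character(scheme_id)) {
    id <- match(scheme_id, names)
    if (is.na(id)) stop("unknown dataset name '", scheme_id, "'")
  } else {
    id <- as.integer(scheme_id)
    if (is.na(id) || id < 1L || id > 4L) stop("scheme_id must be 1..4")
  }
  structure(list(scheme_id = id, dataset_name = names[id],
                 n_bands = bands[id]),
            class = "scheme_spec")
}

#' Build the feature dataset of a classification scheme
#'
#' @param scheme a [scheme_spec()] (or its id/name).
#' @param hms 4-band pansharpened reflectance `raster_stack`.
#' @param vi a [vi_params()].
#' @param lee a [lee_sigma_params()].
#' @return feature `raster_stack` with the scheme's band count (4, 5, 4 or
#'   13).
#' @export
build_dataset <- function(scheme, hms, vi = vi_params(),
                          lee = lee_sigma_params()) {
  if (!inherits(scheme, "scheme_spec")) scheme <- scheme_spec(scheme)
  if (n_bands(hms) != 4L)
    stop("expected the 4-band pansharpened stack, got ", n_bands(hms), " bands")
  out <- switch(scheme$scheme_id,
                hms,
                build_hms5vi(hms, vi),
                build_spectex(hms, lee),
                stack_bands(list(hms, build_hms5vi(hms, vi),
                                 build_spectex(hms, lee))))
  stopifnot(n_bands(out) == scheme$n_bands)
  out
}

#' Run the full classifier-by-scheme comparison experiment
#'
#' The end-to-end pipeline on one scene: pansharpen the multispectral stack
#' with the pan band, build the requested feature datasets, train Gaussian
#' signatures per dataset on species-stratified training samples, classify,
#' and score training-performance and test-accuracy reports for every
#' classifier x scheme combination; finally assemble the AIE table, its
#' two-way factorial ANOVA and the Duncan groupings. A failing combination
#' is recorded and skipped rather than aborting the run.
#'
#' @param scene list with `ms`, `pan`, `labels` (as from
#'   [generate_scene()]), or pre-split `labels_train` / `labels_test`.
#' @param classifiers character vector among `"mlc"`, `"md"`, `"sam"`,
#'   `"sid"`.
#' @param schemes scheme ids or names (default all four).
#' @param n_train,n_test per-species sample sizes drawn from `labels`
#'   (ignored when pre-split labels are given).
#' @param seed seed for the stratified sampling.
#' @param vi,lee parameter objects passed to [build_dataset()].
#' @param classify_maps also produce full label maps (slower); otherwise
#'   only the sample pixels are classified.
#' @return list of class `experiment_result`: `reports` (list of
#'   `accuracy_report`), `summary` (data frame), `td_matrices` (per
#'   scheme), `aie_table`, `anova`, `duncan_datasets`,
#'   `duncan_classifiers`, `errors`, `manifest`.
#' @export
run_experiment <- function(scene, classifiers = c("mlc", "md", "sam", "sid"),
                           schemes = 1:4, n_train = 50L, n_test = 150L,
                           seed = 1L, vi = vi_params(),
                           lee = lee_sigma_params(),
                           classify_maps = FALSE) {
  stopifnot(all(classifiers %in% c("mlc", "md", "sam", "sid")))
  hms <- pct_fuse(scene$ms, scene$pan)
  if (!is.null(scene$labels_train) && !is.null(scene$labels_test)) {
    lab_tr <- scene$labels_train; lab_te <- scene$labels_test
  } else {
    spl <- stratified_sample(scene$labels, counts = n_train + n_test,
                             split = n_train / (n_train + n_test),
                             seed = seed)
    lab_tr <- spl$train; lab_te <- spl$test
  }
  reports <- list(); errors <- list(); td_matrices <- list()
  rows <- list()
  for (sid in schemes) {
    sp <- scheme_spec(sid)
    feat <- build_dataset(sp, hms, vi = vi, lee = lee)
    tr_samples <- extract_samples(feat, lab_tr)
    sigs <- train_signatures(tr_samples)
    td_matrices[[sp$dataset_name]] <- td_matrix(sigs)
    for (cl in classifiers) {
      res <- tryCatch({
        pred <- if (classify_maps) classify(feat, sigs, method = cl)
                else classify_samples(feat, sigs, cl, lab_tr, lab_te)
        for (role in c("training", "test")) {
          lab <- if (role == "training") lab_tr else lab_te
          rep <- accuracy_report(pred, lab, classifier = cl,
                                 dataset = sp$dataset_name, role = role)
          key <- paste(cl, sp$dataset_name, role, sep = "/")
          reports[[key]] <- rep
          rows[[key]] <- data.frame(classifier = cl,
                                    dataset = sp$dataset_name,
                                    role = role, okc = rep$okc,
                                    overall_accuracy = rep$overall_accuracy,
                                    stringsAsFactors = FALSE)
        }
        NULL
      }, error = function(e) conditionMessage(e))
      if (!is.null(res))
        errors[[paste(cl, sp$dataset_name, sep = "/")]] <- res
    }
  }
  summary_df <- do.call(rbind, rows)
  rownames(summary_df) <- NULL
  aie_tab <- anova_res <- dg_data <- dg_class <- NULL
  if (!is.null(summary_df) && "HMS" %in% summary_df$dataset) {
    err <- tryCatch({
      aie_tab <- build_aie_table(summary_df)
      if (length(unique(aie_tab$dataset)) >= 2L &&
          length(unique(aie_tab$classifier)) >= 2L) {
        anova_res <- two_way_anova(aie_tab)
        dg_data <- duncan_aie(aie_tab, anova_res, "dataset")
        dg_class <- duncan_aie(aie_tab, anova_res, "classifier")
      }
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(err)) errors[["aie_stats"]] <- err
  }
  structure(list(reports = reports, summary = summary_df,
                 td_matrices = td_matrices, aie_table = aie_tab,
                 anova = anova_res, duncan_datasets = dg_data,
                 duncan_classifiers = dg_class, errors = errors,
                 manifest = list(seed = seed, classifiers = classifiers,
                                 schemes = schemes, n_train = n_train,
                                 n_test = n_test)),
            class = "experiment_result")
}

# classify only the pixels carrying train/test labels; returns a label map
# with zeros elsewhere (fast path used by run_experiment)
classify_samples <- function(feat, sigs, method, lab_tr, lab_te) {
  sel <- lab_tr$labels > 0L | lab_te$labels > 0L
  d <- dim(feat$data)
  sub_mask <- feat$mask | !sel
  sub <- raster_stack(feat$data, band_names = feat$band_names,
                      pixel_size = feat$pixel_size, mask = sub_mask)
  classify(sub, sigs, method = method)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result>\n")
  if (!is.null(x$summary)) {
    wide <- stats::reshape(x$summary[, c("classifier", "dataset", "role", "okc")],
                           idvar = c("classifier", "dataset"),
                           timevar = "role", direction = "wide")
    names(wide) <- sub("^okc\\.", "okc_", names(wide))
    print(wide, row.names = FALSE)
  }
  if (length(x$errors)) {
    cat("failed combinations:\n")
    for (nm in names(x$errors)) cat("  ", nm, ": ", x$errors[[nm]], "\n", sep = "")
  }
  invisible(x)
}

#' Write the experiment artifacts to a directory
#'
#' CSV tables (per-report summary, AIE, ANOVA, Duncan groupings, per-scheme
#' TD matrices) plus a JSON run manifest.
#'
#' @param x an `experiment_result`.
#' @param dir output directory (created if missing).
#' @param species_table optional table for abbreviated headers.
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(x, dir, species_table = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(x$summary, file.path(dir, "okc_summary.csv"),
                   row.names = FALSE)
  if (!is.null(x$aie_table))
    utils::write.csv(as.data.frame(x$aie_table),
                     file.path(dir, "aie_table.csv"), row.names = FALSE)
  if (!is.null(x$anova))
    utils::write.csv(x$anova$table, file.path(dir, "anova.csv"),
                     row.names = FALSE)
  if (!is.null(x$duncan_datasets))
    utils::write.csv(x$duncan_datasets$groups,
                     file.path(dir, "duncan_datasets.csv"), row.names = FALSE)
  if (!is.null(x$duncan_classifiers))
    utils::write.csv(x$duncan_classifiers$groups,
                     file.path(dir, "duncan_classifiers.csv"), row.names = FALSE)
  for (nm in names(x$td_matrices))
    write_td_csv(x$td_matrices[[nm]],
                 file.path(dir, paste0("td_", nm, ".csv")), species_table)
  jsonlite::write_json(x$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
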