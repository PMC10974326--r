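#' Write the model-comparison report as CSV
#'
#' Columns `Model`, `MeanAccuracy`, `Std` (3 decimals) and, unless
#' suppressed, `FoldTimeSeconds`. Wall-clock timing varies run to run, so
#' determinism checks on reports should use `include_timing = FALSE`.
#'
#' @param cv A [kfold_compare()] result.
#' @param path Output path.
#' @param include_timing Keep the timing column (default TRUE).
#' @param digits Rounding for accuracy columns (default 3).
#' @return `path`, invisibly.
#' @export
write_comparison_csv <- function(cv, path, include_timing = TRUE, digits = 3) {
  out <- cv
  out$MeanAccuracy <- round(out$MeanAccuracy, digits)
  out$Std <- round(out$Std, digits)
  if (include_timing) {
    out$FoldTimeSeconds <- round(out$FoldTimeSeconds, 3)
  } else {
    out$FoldTimeSeconds <- NULL
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write the per-person report as CSV
#'
#' The per-person leave-one-subject-out table rounded to 2 decimals,
#' mirroring the study's printed layout.
#'
#' @param pp A [per_person_eval()] result.
#' @param path Output path.
#' @param digits Rounding (default 2).
#' @return `path`, invisibly.
#' @export
write_per_person_csv <- function(pp, path, digits = 2) {
  out <- pp
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], round, digits = digits)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a machine-readable run manifest
#'
#' JSON record of a comparison run: the resolved model specs (every
#' hyperparameter as fitted), seeds, the fold assignment, and unrounded
#' per-fold accuracies. Wall times are deliberately excluded so the
#' manifest is byte-identical across reruns with the same config and seed.
#'
#' @param cv A [kfold_compare()] result.
#' @param specs The list of [model_spec()]s that produced it.
#' @param path Output path.
#' @param extra Optional named list merged into the manifest (e.g. the
#'   simulation settings).
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(cv, specs, path, extra = list()) {
  manifest <- c(list(
    protocol = sprintf("stratified %d-fold cross-validation", attr(cv, "k")),
    seed = attr(cv, "seed"),
    models = lapply(specs, function(s) {
      list(name = s$name, hyperparameters = s$hyperparameters,
           standardize_inputs = s$standardize_inputs, seed = s$seed)
    }),
    fold_assignment = attr(cv, "fold_assignment"),
    fold_accuracies = as.data.frame(attr(cv, "fold_accuracies")),
    mean_accuracy = as.list(stats::setNames(cv$MeanAccuracy, cv$Model)),
    std_accuracy = as.list(stats::setNames(cv$Std, cv$Model))
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
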