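#' Run the full 2D-QSAR workflow
#'
#' Orchestrates the pipeline end to end: generate (or load) molecules and
#' activities, compute descriptors, split by sorted response, select a
#' descriptor subset by GA, fit the MLR model, validate internally and
#' externally, and compute the applicability domain. Every artifact is
#' written under `out_dir` as plain text (CSV / JSON), and the run is
#' deterministic given `seed`.
#'
#' @param out_dir output directory (created if absent).
#' @param molecules list of `molgraph` objects, or `NULL` to simulate a
#'   54-compound synthetic dataset.
#' @param activities data.frame (`id`, `IC50_uM`) or path to such a CSV;
#'   ignored when simulating.
#' @param seed integer seed controlling simulation, GA and validation.
#' @param ga_generations GA generations per subset size (scaled down from
#'   the 10000 default for interactive runs).
#' @param lmo_iters,yscr_iters validation iteration counts.
#' @param max_size largest GA subset size.
#' @return (invisibly) a list with the fitted `model`, the
#'   `validation_report`, the Williams data and the output paths.
#' @export
run_qsar_workflow <- function(out_dir, molecules = NULL, activities = NULL,
                              seed, ga_generations = 2000L,
                              lmo_iters = 2000L, yscr_iters = 2000L,
                              max_size = 5L) {
  if (missing(seed)) stop("run_qsar_workflow requires an explicit seed")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_line <- function(...) message(sprintf(...))

  if (is.null(molecules)) {
    log_line("stage simulate: generating 54-compound synthetic dataset")
    ds <- generate_2d_dataset(synthetic_spec(seed = seed))
    molecules <- ds$molecules
    act <- ds$activities
    desc <- ds$descriptors
  } else {
    if (is.null(activities)) stop("activities required when molecules given")
    joined <- attach_activities(molecules, activities)
    act <- joined[, c("id", "IC50_uM", "pIC50", "class")]
    log_line("stage descriptors: %d molecules", length(molecules))
    desc <- descriptor_table(molecules)
  }
  utils::write.csv(act, file.path(out_dir, "activities.csv"),
                   row.names = FALSE)
  utils::write.csv(desc, file.path(out_dir, "descriptors.csv"),
                   row.names = FALSE)

  log_line("stage split: sorted-response 70:30")
  sp <- split_sorted_response(act$id, act$pIC50)
  writeLines(jsonlite::toJSON(sp), file.path(out_dir, "split.json"))
  tr <- match(sp$train, desc$id)
  te <- match(sp$test, desc$id)
  d_cols <- setdiff(names(desc), "id")
  X_tr <- desc[tr, d_cols, drop = FALSE]
  y_tr <- act$pIC50[tr]
  X_te <- desc[te, d_cols, drop = FALSE]
  y_te <- act$pIC50[te]

  log_line("stage prefilter + GA-VSS (seed %d)", seed)
  X_f <- descriptor_prefilter(X_tr)
  ranking <- ga_vss(X_f, y_tr, max_size = min(max_size, ncol(X_f)),
                    generations = ga_generations, seed = seed)
  model <- attr(ranking, "model")
  model$ids <- sp$train
  utils::write.csv(ranking, file.path(out_dir, "ga_ranking.csv"),
                   row.names = FALSE)
  write_model_json(model, file.path(out_dir, "model.json"), seed = seed)

  log_line("stage validate")
  report <- validation_report(model,
                              X_ext = X_te[, model$descriptors, drop = FALSE],
                              y_ext = y_te, lmo_iters = lmo_iters,
                              yscr_iters = yscr_iters, seed = seed + 1L)
  writeLines(jsonlite::toJSON(unclass(report), auto_unbox = TRUE,
                              digits = NA, null = "null"),
             file.path(out_dir, "validation.json"))

  log_line("stage applicability domain")
  wd <- williams_data(model,
                      external = list(X = X_te[, model$descriptors,
                                               drop = FALSE],
                                      y = y_te, ids = sp$test))
  utils::write.csv(wd, file.path(out_dir, "williams.csv"), row.names = FALSE)

  invisible(list(model = model, report = report, williams = wd,
                 split = sp, out_dir = out_dir))
}

#' Predict activities for new molecules with domain flags
#'
#' Computes descriptors for new molecules, predicts pIC50 and IC50 with a
#' fitted (or the published) model, and flags whether each compound lies in
#' the leverage-based applicability domain (when the model carries a
#' training design). Molecules whose descriptors fail are kept as rows with
#' `NA` values and the error message in `note`.
#'
#' @param model a `qsar_mlr`.
#' @param molecules list of `molgraph` objects.
#' @return data.frame: id, the five descriptors, predicted pIC50, predicted
#'   IC50 (uM), `in_domain` (NA when the model has no training design),
#'   `note`.
#' @export
predict_new <- function(model, molecules) {
  rows <- lapply(molecules, function(g) {
    dv <- tryCatch(suppressWarnings(descriptor_vector(g)),
                   error = function(e) conditionMessage(e))
    if (is.character(dv)) {
      out <- as.data.frame(as.list(stats::setNames(
        rep(NA_real_, length(model$descriptors)), model$descriptors)))
      out$id <- g$id; out$note <- dv
      return(out)
    }
    out <- as.data.frame(as.list(dv))
    out$id <- g$id; out$note <- ""
    out
  })
  tab <- do.call(rbind, rows)
  tab <- tab[, c("id", setdiff(names(tab), c("id", "note")), "note")]
  ok <- stats::complete.cases(tab[, model$descriptors, drop = FALSE])
  tab$pIC50_pred <- NA_real_
  tab$IC50_uM_pred <- NA_real_
  tab$in_domain <- NA
  if (any(ok)) {
    preds <- predict(model, tab[ok, , drop = FALSE])
    tab$pIC50_pred[ok] <- preds
    tab$IC50_uM_pred[ok] <- ic50_from_pic50(preds)
    if (!is.null(model$X)) {
      ins <- insubria_data(model, tab[ok, model$descriptors, drop = FALSE],
                           ids = tab$id[ok])
      tab$in_domain[ok] <- ins$in_domain
    }
  }
  rownames(tab) <- NULL
  tab
}
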