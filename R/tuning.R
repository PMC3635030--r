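#' Sample a holdout subset of subjects
#'
#' Subjects are drawn without replacement with a logged seed; the
#' remaining analysis conventionally re-applies the tuned parameters to
#' the *full* dataset (including the holdout), which induces a mild
#' optimism documented in the package README.
#'
#' @param data A [grouped_dataset()].
#' @param n_subjects Holdout size.
#' @param seed Integer seed for the draw.
#' @return List with `holdout` (a `grouped_dataset` restricted to the
#'   sampled subjects), `subjects` (their ids) and `seed`.
#' @export
sample_holdout <- function(data, n_subjects, seed = 1L) {
  assert_that(inherits(data, "grouped_dataset"), "`data` must be grouped")
  assert_that(is_count(n_subjects) && n_subjects <= length(data$subjects),
              "`n_subjects` must be <= the number of subjects")
  chosen <- with_seed(seed, sort(sample(data$subjects, n_subjects)))
  rows <- data$subject %in% chosen
  list(holdout = grouped_dataset(data$X[rows, , drop = FALSE],
                                 data$subject[rows],
                                 label = data$label[rows],
                                 age = data$age[rows]),
       subjects = chosen, seed = as.integer(seed))
}

new_tuning_grid <- function(cells, metric, best_row) {
  structure(list(cells = cells, metric = metric, best = cells[best_row, ]),
            class = "tuning_grid")
}

#' @export
print.tuning_grid <- function(x, ...) {
  cat("<tuning_grid> ", nrow(x$cells), " cells, metric = ", x$metric,
      "\n  best: ", paste(names(x$best), unlist(lapply(x$best, format,
                                                       digits = 4)),
                          sep = " = ", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Holdout grid search for the classifier
#'
#' Evaluates subject-grouped LOOCV accuracy on the holdout set at every
#' `(k, C)` cell and returns the grid with its argmax (ties broken by
#' smaller `k`, then smaller `C`, so tuning is deterministic).
#'
#' @param holdout A [grouped_dataset()] (typically from
#'   [sample_holdout()]).
#' @param k_grid Feature counts to try.
#' @param C_grid Penalties to try.
#' @param kernel A [kernel_spec()].
#' @return A `tuning_grid` whose cells carry `k`, `C`, `accuracy`.
#' @export
grid_search_classifier <- function(holdout, k_grid, C_grid,
                                   kernel = kernel_spec("linear")) {
  assert_that(length(k_grid) >= 1 && length(C_grid) >= 1,
              "grids must be nonempty")
  cells <- expand.grid(k = sort(k_grid), C = sort(C_grid),
                       KEEP.OUT.ATTRS = FALSE)
  cells <- cells[order(cells$k, cells$C), , drop = FALSE]
  cells$accuracy <- vapply(seq_len(nrow(cells)), function(r) {
    loocv_classify(holdout, k = cells$k[r], C = cells$C[r],
                   kernel = kernel)$accuracy
  }, 0)
  rownames(cells) <- NULL
  new_tuning_grid(cells, "accuracy", which.max(cells$accuracy))
}

#' Holdout grid search for the SVR age predictor
#'
#' Evaluates LOOCV regression performance on the holdout at every
#' `(k, epsilon)` cell.  The argmax is by slope of the predicted-vs-
#' true line (the closer to 1 the better the predictor, up to the
#' shrinkage all such predictors show), with ties broken by larger
#' R-squared, then smaller `k`.
#'
#' @param holdout A [grouped_dataset()] with ages.
#' @param k_grid Feature counts to try.
#' @param eps_grid Tube half-widths to try.
#' @param C Penalty (fixed across the grid).
#' @return A `tuning_grid` whose cells carry `k`, `epsilon`, `slope`,
#'   `r_squared`.
#' @export
grid_search_svr <- function(holdout, k_grid, eps_grid, C = 1) {
  assert_that(length(k_grid) >= 1 && length(eps_grid) >= 1,
              "grids must be nonempty")
  cells <- expand.grid(k = sort(k_grid), epsilon = sort(eps_grid),
                       KEEP.OUT.ATTRS = FALSE)
  cells <- cells[order(cells$k, cells$epsilon), , drop = FALSE]
  res <- lapply(seq_len(nrow(cells)), function(r) {
    reg <- loocv_svr(holdout, k = cells$k[r], C = C,
                     epsilon = cells$epsilon[r])$regression
    c(slope = reg$slope, r_squared = reg$r_squared)
  })
  cells$slope <- vapply(res, `[[`, 0, "slope")
  cells$r_squared <- vapply(res, `[[`, 0, "r_squared")
  rownames(cells) <- NULL
  ord <- order(-cells$slope, -cells$r_squared, cells$k)
  new_tuning_grid(cells, "slope", ord[1])
}

#' Write a tuning grid to CSV
#'
#' @param grid A `tuning_grid`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tuning_grid <- function(grid, path) {
  assert_that(inherits(grid, "tuning_grid"), "`grid` must be a tuning_grid")
  write.csv(grid$cells, path, row.names = FALSE)
  invisible(path)
}
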