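#' Generate a randomized block exposure design
#'
#' Builds the exposure schedule for one specimen: `n_blocks` independent
#' uniform-random permutations of the solution ids, strung together, so each
#' consecutive block of trials uses every solution exactly once. With the
#' default six solutions and five blocks this yields the canonical 30-trial
#' session. Every trial carries a fixed exposure duration and a recovery
#' interval (default 60 s) during which the specimen hangs in clean air.
#'
#' @param n_blocks number of permutation blocks (>= 0).
#' @param solutions list of [solution_composition()] objects with distinct ids;
#'   defaults to all six built-in mixtures.
#' @param seed integer seed; the design is deterministic given the seed.
#' @param exposure_s exposure duration per trial in seconds.
#' @param recovery_s recovery interval between trials in seconds.
#' @param specimen_id label recorded in the design.
#' @return An object of class `"exposure_design"`: a data.frame with columns
#'   `trial_index`, `solution_id`, `exposure_s`, `recovery_s`, plus attributes
#'   `solutions`, `n_blocks`, `specimen_id`, `seed`.
#' @examples
#' d <- generate_exposure_design(n_blocks = 5, seed = 1)
#' nrow(d)           # 30 trials
#' table(d$solution_id)
#' @export
generate_exposure_design <- function(n_blocks, solutions = NULL, seed = NULL,
                                     exposure_s = 180, recovery_s = 60,
                                     specimen_id = "specimen-1") {
  if (is.null(solutions))
    solutions <- lapply(1:6, solution_composition)
  if (length(solutions) == 0L)
    stopf("at least one solution is required")
  ids <- vapply(solutions, function(s) s$solution_id, integer(1))
  if (anyDuplicated(ids))
    stopf("duplicate solution ids in `solutions`: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (n_blocks < 0 || n_blocks != round(n_blocks))
    stopf("n_blocks must be a non-negative integer")

  order_ids <- with_seed(seed, {
    unlist(lapply(seq_len(n_blocks), function(b) ids[sample.int(length(ids))]),
           use.names = FALSE)
  })
  if (is.null(order_ids)) order_ids <- integer(0)

  d <- data.frame(
    trial_index = seq_along(order_ids),
    solution_id = as.integer(order_ids),
    exposure_s = rep(exposure_s, length(order_ids)),
    recovery_s = rep(recovery_s, length(order_ids))
  )
  structure(d,
            class = c("exposure_design", "data.frame"),
            solutions = solutions, n_blocks = as.integer(n_blocks),
            specimen_id = specimen_id, seed = seed)
}

#' @export
print.exposure_design <- function(x, ...) {
  cat(sprintf("Exposure design for %s: %d trials (%d blocks x %d solutions)\n",
              attr(x, "specimen_id"), nrow(x), attr(x, "n_blocks"),
              length(attr(x, "solutions"))))
  if (nrow(x) > 0)
    cat("  order:", paste(x$solution_id, collapse = " "), "\n")
  invisible(x)
}

# composition lookup table (rows aligned with design trials)
design_fractions <- function(design) {
  sols <- attr(design, "solutions")
  ids <- vapply(sols, function(s) s$solution_id, integer(1))
  idx <- match(design$solution_id, ids)
  data.frame(
    trial_index = design$trial_index,
    solution_id = design$solution_id,
    f_acetone = vapply(sols, function(s) s$f_acetone, numeric(1))[idx],
    f_ethanol = vapply(sols, function(s) s$f_ethanol, numeric(1))[idx],
    f_water = vapply(sols, function(s) s$f_water, numeric(1))[idx]
  )
}

#' Read or write an exposure design as CSV
#'
#' The on-disk format has columns `trial_index, solution_id, exposure_s,
#' recovery_s`. Reading reconstructs the compositions from the built-in
#' solution table.
#'
#' @param design an `exposure_design`.
#' @param path CSV file path.
#' @return `read_exposure_design` returns an `exposure_design`.
#' @export
write_exposure_design <- function(design, path) {
  write.csv(as.data.frame(design)[, c("trial_index", "solution_id",
                                      "exposure_s", "recovery_s")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_exposure_design
#' @export
read_exposure_design <- function(path) {
  d <- read.csv(path)
  need <- c("trial_index", "solution_id", "exposure_s", "recovery_s")
  if (!all(need %in% names(d)))
    stopf("design file missing columns: %s",
          paste(setdiff(need, names(d)), collapse = ", "))
  sols <- lapply(sort(unique(d$solution_id)), solution_composition)
  nb <- if (nrow(d) %% max(1, length(sols)) == 0L)
    nrow(d) %/% max(1, length(sols)) else NA_integer_
  structure(d[, need],
            class = c("exposure_design", "data.frame"),
            solutions = sols, n_blocks = nb,
            specimen_id = "from-file", seed = NULL)
}
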