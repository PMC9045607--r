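#' Headspace solution compositions
#'
#' The six solvent mixtures whose headspaces the films are exposed to, encoded
#' as component volumes and volume fractions of acetone, ethanol and water.
#' Pure solvents use 60 mL; binary mixtures 30 mL + 30 mL; the ternary mixture
#' 20 mL of each component.
#'
#' @param solution_id integer in 1..6 identifying the mixture.
#' @return For `solution_composition`, a list of class `"solution_composition"`
#'   with fields `solution_id`, `volumes_mL` (named numeric: acetone, ethanol,
#'   water) and `f_acetone`, `f_ethanol`, `f_water` (volume fractions summing
#'   to 1). For `solution_table`, a data.frame with one row per solution.
#' @examples
#' solution_composition(4)      # 30 mL acetone + 30 mL water
#' solution_table()
#' @export
solution_composition <- function(solution_id) {
  tab <- .solution_volumes()
  if (length(solution_id) != 1L || !solution_id %in% seq_len(nrow(tab)))
    stopf("unknown solution_id %s (must be one of 1..%d)",
          paste(solution_id, collapse = ","), nrow(tab))
  v <- unlist(tab[solution_id, c("acetone_mL", "ethanol_mL", "water_mL")])
  names(v) <- c("acetone", "ethanol", "water")
  f <- v / sum(v)
  structure(list(
    solution_id = as.integer(solution_id),
    volumes_mL = v,
    f_acetone = unname(f["acetone"]),
    f_ethanol = unname(f["ethanol"]),
    f_water = unname(f["water"])
  ), class = "solution_composition")
}

# component volumes in mL for the six headspace environments
.solution_volumes <- function() {
  data.frame(
    solution_id = 1:6,
    acetone_mL = c(60, 0, 30, 30, 0, 20),
    ethanol_mL = c(0, 60, 30, 0, 30, 20),
    water_mL   = c(0, 0, 0, 30, 30, 20)
  )
}

#' @rdname solution_composition
#' @export
solution_table <- function() {
  tab <- .solution_volumes()
  tot <- tab$acetone_mL + tab$ethanol_mL + tab$water_mL
  tab$f_acetone <- tab$acetone_mL / tot
  tab$f_ethanol <- tab$ethanol_mL / tot
  tab$f_water <- tab$water_mL / tot
  tab
}

#' Construct a custom solution composition
#'
#' For compositions outside the built-in table (including an empty flask with
#' zero volumes, whose fractions are defined as 0).
#'
#' @param solution_id integer label.
#' @param acetone_mL,ethanol_mL,water_mL component volumes, mL (>= 0).
#' @return A `"solution_composition"`.
#' @export
new_solution <- function(solution_id, acetone_mL = 0, ethanol_mL = 0,
                         water_mL = 0) {
  v <- c(acetone = acetone_mL, ethanol = ethanol_mL, water = water_mL)
  if (any(v < 0)) stopf("volumes must be non-negative")
  f <- if (sum(v) > 0) v / sum(v) else c(acetone = 0, ethanol = 0, water = 0)
  structure(list(solution_id = as.integer(solution_id), volumes_mL = v,
                 f_acetone = unname(f["acetone"]),
                 f_ethanol = unname(f["ethanol"]),
                 f_water = unname(f["water"])),
            class = "solution_composition")
}

#' @export
print.solution_composition <- function(x, ...) {
  cat(sprintf("Solution %d: %g mL acetone + %g mL ethanol + %g mL water\n",
              x$solution_id, x$volumes_mL["acetone"], x$volumes_mL["ethanol"],
              x$volumes_mL["water"]))
  cat(sprintf("  fractions: acetone %.3f, ethanol %.3f, water %.3f\n",
              x$f_acetone, x$f_ethanol, x$f_water))
  invisible(x)
}
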