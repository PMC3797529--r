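#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a satellite profile into a per-position tibble
#'
#' @param x A `sat_profile`.
#' @param ... Unused.
#' @return Tibble with `position`, emission scores `A`, `C`, `G`, `T`,
#'   `consensus` and `best_score`.
#' @export
tidy.sat_profile <- function(x, ...) {
  emis <- x$emissions[, c("A", "C", "G", "T"), drop = FALSE]
  tibble::tibble(
    position = seq_len(x$L),
    A = emis[, "A"], C = emis[, "C"], G = emis[, "G"], T = emis[, "T"],
    consensus = strsplit(x$consensus, "", fixed = TRUE)[[1]],
    best_score = apply(emis, 1, max)
  )
}

#' @rdname tidy.sat_profile
#' @return `glance()` returns a one-row tibble: `n_positions`,
#'   `n_seed_rows`, `self_score`, `gc_consensus`.
#' @export
glance.sat_profile <- function(x, ...) {
  tibble::tibble(
    n_positions = x$L,
    n_seed_rows = x$n_seed_rows,
    self_score = x$self_score,
    gc_consensus = mean(strsplit(x$consensus, "", fixed = TRUE)[[1]] %in% c("G", "C"))
  )
}

#' Tidy major clades into a unit-level tibble
#'
#' @param x A `sat_clades` object.
#' @param ... Unused.
#' @return `tidy()`: tibble `clade`, `unit`, with clade `size` and
#'   `support` joined on; `glance()`: one row with `n_clades`, `n_placed`,
#'   `n_unplaced`, `min_support`, `min_size`.
#' @export
tidy.sat_clades <- function(x, ...) {
  dplyr::left_join(x$members, x$clades, by = "clade")
}

#' @rdname tidy.sat_clades
#' @export
glance.sat_clades <- function(x, ...) {
  tibble::tibble(
    n_clades = nrow(x$clades),
    n_placed = nrow(x$members),
    n_unplaced = length(x$unplaced),
    min_support = x$min_support,
    min_size = x$min_size
  )
}

#' Tidy a recombination screen into its call table
#'
#' @param x A `sat_screen` object.
#' @param ... Unused.
#' @return `tidy()`: the call tibble; `glance()`: one row with `n_tests`,
#'   `n_accepted`, `n_removed`, `alpha`.
#' @export
tidy.sat_screen <- function(x, ...) x$calls

#' @rdname tidy.sat_screen
#' @export
glance.sat_screen <- function(x, ...) {
  tibble::tibble(
    n_tests = x$n_tests,
    n_accepted = sum(x$calls$accepted),
    n_removed = length(x$removed),
    alpha = x$alpha
  )
}
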