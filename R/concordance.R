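#' Cross-tabulate phylogenetic clades against chromosomal locations
#'
#' A location is the chromosome-arm label: the two-digit chromosome label
#' followed by the arm code, e.g. `"10L"` or `"04S"`; centromeric units
#' aggregate into one `C` location per chromosome (`"08C"`). Marginals are
#' checked: per-clade sums equal clade sizes and per-location sums equal
#' the analysed unit counts.
#'
#' @param clades A `sat_clades` object (or its `members` tibble with
#'   columns `clade`, `unit`).
#' @param arms Tibble mapping units to locations: columns `name` (unit
#'   name) plus either `location` or `seq_id` + `arm`.
#' @return A long tibble `clade`, `location`, `n` (only nonzero cells);
#'   pivot wide for the matrix layout.
#' @export
cross_tab <- function(clades, arms) {
  members <- if (inherits(clades, "sat_clades")) clades$members else tibble::as_tibble(clades)
  arms <- tibble::as_tibble(arms)
  if (!"location" %in% names(arms)) {
    stopifnot(all(c("seq_id", "arm") %in% names(arms)))
    arms$location <- paste0(chrom_label(arms$seq_id), arms$arm)
  }
  key <- if ("name" %in% names(arms)) "name" else "unit_key"
  lookup <- stats::setNames(arms$location, arms[[key]])
  missing <- setdiff(members$unit, names(lookup))
  if (length(missing) > 0) {
    stop("unit(s) without an arm assignment: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  tab <- members |>
    dplyr::mutate(location = unname(lookup[.data$unit])) |>
    dplyr::count(.data$clade, .data$location)
  # marginal conservation is structural; verify anyway
  stopifnot(sum(tab$n) == nrow(members))
  tab
}

#' Spreading and local-duplication metrics from a clade-location table
#'
#' Quantifies the two expansion modes of a subtelomeric satellite:
#' interchromosomal spreading (a clade present on two or more locations)
#' and local duplication (a clade dominated by one location).
#'
#' @param tab Long tibble from [cross_tab()].
#' @param spread_min_arms A clade on at least this many distinct locations
#'   counts as spread.
#' @param dominance_threshold A clade whose largest location holds at least
#'   this fraction of its units counts as locally duplicated.
#' @return A list with `clades` (per-clade `n_units`, `n_arms`,
#'   `dominance`), `arms` (per-location `n_clades`), and `summary`
#'   (one row: `n_clades`, `n_spread_clades`, `n_local_clades`,
#'   `median_arms_per_clade`).
#' @export
spread_metrics <- function(tab, spread_min_arms = 2, dominance_threshold = 0.8) {
  tab <- tibble::as_tibble(tab)
  if (nrow(tab) == 0) stop("empty clade-location table")
  clades <- tab |>
    dplyr::group_by(.data$clade) |>
    dplyr::summarise(
      n_units = sum(.data$n),
      n_arms = dplyr::n_distinct(.data$location),
      dominance = max(.data$n) / sum(.data$n),
      .groups = "drop"
    )
  arms <- tab |>
    dplyr::group_by(location = .data$location) |>
    dplyr::summarise(n_clades = dplyr::n_distinct(.data$clade), .groups = "drop")
  summary <- tibble::tibble(
    n_clades = nrow(clades),
    n_spread_clades = sum(clades$n_arms >= spread_min_arms),
    n_local_clades = sum(clades$dominance >= dominance_threshold),
    median_arms_per_clade = stats::median(clades$n_arms)
  )
  list(clades = clades, arms = arms, summary = summary)
}

#' Centromere-subtelomere exchange report
#'
#' Lists clades containing both centromere-assigned (`C`) and arm-assigned
#' (`S`/`L`) units -- the signature of sequence exchange between
#' centromeres and subtelomeres -- with the arms co-occurring with the
#' centromeric units, and flags whether all centromeric units fall into a
#' single clade.
#'
#' @param tab Long tibble from [cross_tab()].
#' @return A list with `exchange` (tibble `clade`, `n_cent_units`,
#'   `co_arms`) and `single_clade` (`TRUE` when every centromeric unit sits
#'   in one clade; `NA` when there are no centromeric units).
#' @export
centromere_exchange <- function(tab) {
  tab <- tibble::as_tibble(tab)
  tab$is_cent <- grepl("C$", tab$location)
  cent_clades <- unique(tab$clade[tab$is_cent & tab$n > 0])
  if (length(cent_clades) == 0) {
    return(list(
      exchange = tibble::tibble(clade = character(), n_cent_units = integer(),
                                co_arms = character()),
      single_clade = NA
    ))
  }
  exchange <- tab |>
    dplyr::filter(.data$clade %in% cent_clades) |>
    dplyr::group_by(.data$clade) |>
    dplyr::summarise(
      n_cent_units = sum(.data$n[.data$is_cent]),
      n_arm_units = sum(.data$n[!.data$is_cent]),
      co_arms = paste(sort(unique(.data$location[!.data$is_cent])), collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_arm_units > 0) |>
    dplyr::select("clade", "n_cent_units", "co_arms")
  list(exchange = exchange, single_clade = length(cent_clades) == 1L)
}
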