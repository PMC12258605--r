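# Repertoire summary statistics: NB-type and domain-category shares,
# cross-tabulations, the realized combination space, and the MCL
# inflation-parameter plateau selector.

#' Summarise an NLR repertoire
#'
#' Counts and percentage shares by NB type, N-terminal category and
#' C-terminal category, plus NB x N-terminal and NB x C-terminal
#' cross-tabs. NB-type shares are rounded to one decimal, cross-tab row
#' shares to integers, both half away from zero -- the conventions of the
#' tables this package reproduces.
#'
#' @param records A tibble of NLR records with columns `nb_type`,
#'   `nterm_category`, `cterm_category` (any may contain `NA`).
#' @return A list of tibbles: `by_nb`, `by_nterm`, `by_cterm`,
#'   `nb_by_nterm`, `nb_by_cterm`. Empty input gives empty tibbles.
#' @examples
#' recs <- tibble::tibble(
#'   nb_type = rep(c("T-NACHT", "NB-ARC"), c(3, 1)),
#'   nterm_category = "sesB-like", cterm_category = "Ankyrin")
#' summarize_repertoire(recs)$by_nb
#' @export
summarize_repertoire <- function(records) {
  records <- as_tibble(records)
  share_table <- function(col, digits) {
    if (nrow(records) == 0) {
      return(tibble(!!col := character(), n = integer(), pct = double()))
    }
    records |>
      filter(!is.na(.data[[col]])) |>
      count(.data[[col]], name = "n") |>
      mutate(pct = round_half_up(100 * .data$n / sum(.data$n), digits)) |>
      arrange(dplyr::desc(.data$n))
  }
  cross_table <- function(col) {
    if (nrow(records) == 0) {
      return(tibble(!!col := character(), nb_type = character(),
                    n = integer(), pct = double()))
    }
    records |>
      filter(!is.na(.data[[col]]), !is.na(.data$nb_type)) |>
      count(.data[[col]], .data$nb_type, name = "n") |>
      group_by(.data[[col]]) |>
      mutate(pct = round_half_up(100 * .data$n / sum(.data$n), 0)) |>
      ungroup() |>
      arrange(.data[[col]], dplyr::desc(.data$n))
  }
  list(by_nb = share_table("nb_type", 1),
       by_nterm = share_table("nterm_category", 1),
       by_cterm = share_table("cterm_category", 1),
       nb_by_nterm = cross_table("nterm_category"),
       nb_by_cterm = cross_table("cterm_category"))
}

#' Possible and realized domain-combination space
#'
#' With `n_nterm` canonical N-terminal categories, `n_nb` NB types and
#' `n_cterm` canonical C-terminal categories, there are
#' `n_nterm * n_nb` possible N-terminal/NB combinations, `n_nb * n_cterm`
#' NB/C-terminal combinations and the product of all three possible
#' tripartite architectures. Observed counts are the distinct tuples in
#' `observed`.
#'
#' @param n_nterm,n_nb,n_cterm Category counts (>= 1).
#' @param observed A data frame of observed architectures with columns
#'   `nterm`, `nb`, `cterm` (rows need not be distinct).
#' @return A one-row tibble with possible and observed counts for the two
#'   pairwise spaces and the tripartite space, and the realized tripartite
#'   proportion in percent.
#' @examples
#' combination_space(8, 3, 4,
#'   observed = tibble::tibble(nterm = "sesB-like", nb = "T-NACHT",
#'                             cterm = "Ankyrin"))
#' @export
combination_space <- function(n_nterm, n_nb, n_cterm, observed) {
  stopifnot(n_nterm >= 1, n_nb >= 1, n_cterm >= 1)
  observed <- as_tibble(observed)
  obs_nn <- nrow(distinct(observed, .data$nterm, .data$nb))
  obs_nc <- nrow(distinct(observed, .data$nb, .data$cterm))
  obs_tri <- nrow(distinct(observed, .data$nterm, .data$nb, .data$cterm))
  if (nrow(observed) == 0) obs_nn <- obs_nc <- obs_tri <- 0L
  possible_tri <- n_nterm * n_nb * n_cterm
  tibble(possible_nterm_nb = n_nterm * n_nb,
         possible_nb_cterm = n_nb * n_cterm,
         possible_tripartite = possible_tri,
         observed_nterm_nb = obs_nn,
         observed_nb_cterm = obs_nc,
         observed_tripartite = obs_tri,
         realized_tripartite_pct = 100 * obs_tri / possible_tri)
}

#' Select the MCL inflation parameter at the first count plateau
#'
#' Given the number of NLRs in the largest ortholog groups for each tested
#' inflation value, returns the first inflation value of the earliest run
#' of at least three consecutive equal counts. With no plateau, returns
#' `NA` with a warning.
#'
#' @param table A data frame with columns `inflation` (strictly
#'   increasing) and `count`.
#' @return The selected inflation value (`NA_real_` if no plateau exists).
#' @examples
#' plateau_select_inflation(
#'   data.frame(inflation = c(0.5, 1, 1.5, 2, 2.5),
#'              count = c(12, 10, 9, 9, 9)))
#' @export
plateau_select_inflation <- function(table) {
  table <- as_tibble(table)
  stopifnot(all(c("inflation", "count") %in% names(table)))
  if (nrow(table) < 3) abort("Need at least three inflation values to find a plateau.")
  if (any(diff(table$inflation) <= 0)) abort("`inflation` must be strictly increasing.")
  for (i in seq_len(nrow(table) - 2)) {
    if (table$count[i] == table$count[i + 1] && table$count[i] == table$count[i + 2]) {
      return(table$inflation[i])
    }
  }
  warn("No plateau of three consecutive equal counts; no inflation value selected.")
  NA_real_
}
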