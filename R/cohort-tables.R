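# The published cohort allocation: donor and cell counts per donor-disjoint
# split, at the class level (fetal F / adult A), as printed in the study the
# pipeline reimplements.  These counts are inputs to the cohort-arithmetic
# checks and to the construction of a size-matched synthetic cohort.

#' Published cohort split allocation
#'
#' Donor and cell counts of the five donor-disjoint splits (four
#' training/validation sets and one test set) of the 164-donor cohort,
#' together with the printed percentages of the overall totals.
#'
#' @return A data frame with one row per split (`set1`..`set4`, `test`) and
#'   columns `donors`, `donors_f`, `donors_a`, `cells`, `cells_f`,
#'   `cells_a`, plus the printed percentage columns `pct_*`.
#' @export
published_split_table <- function() {
  data.frame(
    split = c("set1", "set2", "set3", "set4", "test"),
    donors = c(32L, 34L, 32L, 34L, 32L),
    donors_f = c(12L, 13L, 17L, 10L, 13L),
    donors_a = c(20L, 21L, 15L, 24L, 19L),
    cells = c(5240L, 5613L, 5250L, 5585L, 5538L),
    cells_f = c(1976L, 2233L, 2707L, 1553L, 2134L),
    cells_a = c(3264L, 3380L, 2543L, 4032L, 3404L),
    pct_donors = c(19.51, 20.73, 19.51, 20.73, 19.51),
    pct_donors_f = c(18.46, 20, 26.15, 15.38, 20),
    pct_donors_a = c(20.2, 21.21, 15.15, 24.24, 19.19),
    pct_cells = c(19.25, 20.62, 19.28, 20.51, 20.34),
    pct_cells_f = c(18.64, 21.06, 25.53, 14.65, 20.13),
    pct_cells_a = c(19.64, 20.33, 15.3, 24.26, 20.48),
    stringsAsFactors = FALSE
  )
}

#' Cohort arithmetic from the published split table
#'
#' Sums the per-split donor and cell counts and recomputes every split's
#' percentage of the totals, for comparison with the printed values.
#'
#' @param table Split table as returned by [published_split_table()].
#' @return A list with `totals` (donors/cells overall and per class, plus
#'   the adult share of cells in percent) and `splits` (the table augmented
#'   with recomputed percentage columns `rpct_*`).
#' @export
cohort_arithmetic <- function(table = published_split_table()) {
  tot <- list(
    donors = sum(table$donors),
    donors_f = sum(table$donors_f),
    donors_a = sum(table$donors_a),
    cells = sum(table$cells),
    cells_f = sum(table$cells_f),
    cells_a = sum(table$cells_a)
  )
  tot$adult_cell_share_pct <- 100 * tot$cells_a / tot$cells
  splits <- table
  splits$rpct_donors <- 100 * table$donors / tot$donors
  splits$rpct_donors_f <- 100 * table$donors_f / tot$donors_f
  splits$rpct_donors_a <- 100 * table$donors_a / tot$donors_a
  splits$rpct_cells <- 100 * table$cells / tot$cells
  splits$rpct_cells_f <- 100 * table$cells_f / tot$cells_f
  splits$rpct_cells_a <- 100 * table$cells_a / tot$cells_a
  list(totals = tot, splits = splits)
}

#' Donor specifications matching the published cohort sizes
#'
#' Builds one [donor_spec()] per donor of the published cohort, with each
#' split's class-level cell total distributed as evenly as possible across
#' its donors, so that the manifest reproduces the published per-split and
#' overall cell counts exactly.
#'
#' @param table Split table as returned by [published_split_table()].
#' @return A list of `donor_spec` objects (length 164 for the published
#'   table) with an attribute `split` giving each donor's split.
#' @export
published_cohort_donors <- function(table = published_split_table()) {
  donors <- list()
  split_of <- character(0)
  even_sizes <- function(total, k) {
    base <- total %/% k
    sizes <- rep(base, k)
    extra <- total - base * k
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    as.integer(sizes)
  }
  for (i in seq_len(nrow(table))) {
    row <- table[i, ]
    for (cls in c("f", "a")) {
      nd <- row[[paste0("donors_", cls)]]
      nc <- row[[paste0("cells_", cls)]]
      if (nd == 0) next
      sizes <- even_sizes(nc, nd)
      lab <- if (cls == "f") "fetal" else "adult"
      for (j in seq_len(nd)) {
        id <- sprintf("%s_%s%02d", row$split, cls, j)
        donors[[length(donors) + 1L]] <- donor_spec(
          id, class_label = lab, n_cells = sizes[j])
        split_of <- c(split_of, row$split)
      }
    }
  }
  attr(donors, "split") <- split_of
  donors
}
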