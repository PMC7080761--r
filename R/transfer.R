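#' Input ratio of a competitive adoptive transfer
#'
#' The pre-transfer donor-to-competitor ratio: the number of donor
#' (CD45.2 YFP+) cells divided by the number of competitor (CD45.1+) cells
#' measured in the saved input aliquot. A 1:1 input mix has IR = 1.
#'
#' @param n_donor_a Donor cell count (CD45.2 YFP+ analog), >= 0.
#' @param n_donor_b Competitor cell count (CD45.1+ analog), > 0.
#' @return The scalar input ratio.
#' @export
input_ratio <- function(n_donor_a, n_donor_b) {
  stopifnot(n_donor_a >= 0)
  if (n_donor_b <= 0) stop("competitor count must be positive")
  n_donor_a / n_donor_b
}

#' Input-ratio-normalized recovery
#'
#' The recovered donor-to-competitor ratio divided by the input ratio, so a
#' value of 1 means recovery proportional to the input mix. Scale-invariant:
#' multiplying both recovered counts by a constant leaves the result
#' unchanged. Populations with a zero competitor count (an empty gate) give
#' `NA` rather than 0 or infinity.
#'
#' @param n_donor_a,n_donor_b Recovered donor / competitor counts.
#' @param ir Input ratio from [input_ratio()], > 0.
#' @return The normalized recovery scalar, or `NA` for an empty gate.
#' @export
normalized_recovery <- function(n_donor_a, n_donor_b, ir) {
  if (ir <= 0) stop("input ratio must be positive")
  if (n_donor_b == 0) return(NA_real_)
  (n_donor_a / n_donor_b) / ir
}

#' Normalize a table of transfer counts
#'
#' Tabular front-end: takes per-population recovered counts plus the input
#' counts and returns the normalized recovery per population.
#'
#' @param recovered A data frame with columns `population`, `n_donor_a`,
#'   `n_donor_b`.
#' @param input_a,input_b Pre-transfer input counts.
#' @return A tibble with the input ratio and per-population `ratio` and
#'   `normalized` columns.
#' @export
transfer_table <- function(recovered, input_a, input_b) {
  ir <- input_ratio(input_a, input_b)
  recovered |>
    tibble::as_tibble() |>
    dplyr::mutate(
      ratio = ifelse(.data$n_donor_b > 0,
                     .data$n_donor_a / .data$n_donor_b, NA_real_),
      input_ratio = ir,
      normalized = .data$ratio / ir
    )
}
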