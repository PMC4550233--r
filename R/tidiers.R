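#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a puff analysis into a per-event table
#'
#' @param x A [analyze_puffs()] result.
#' @param ... Unused.
#' @return The per-event tibble (`site_id`, `event`, windows, amplitudes in
#'   each mode, `ratio`, `included`).
#' @export
tidy.puff_analysis <- function(x, ...) x$events

#' One-row summary of a puff analysis
#'
#' @param x A [analyze_puffs()] result.
#' @param ... Unused.
#' @return A one-row tibble: `n_events`, `n_sites`, `mean_ratio`,
#'   `fraction_gt_1`, `n_superficial`, `n_intermediate`, `n_deep`.
#' @export
glance.puff_analysis <- function(x, ...) {
  tibble::tibble(
    n_events = sum(x$events$included),
    n_sites = nrow(x$sites),
    mean_ratio = mean(x$events$ratio, na.rm = TRUE),
    fraction_gt_1 = x$histogram$fraction_gt_1,
    n_superficial = sum(x$sites$class == "superficial"),
    n_intermediate = sum(x$sites$class == "intermediate"),
    n_deep = sum(x$sites$class == "deep")
  )
}
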