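#' Shortest closed tour through a set of points
#'
#' Length of the shortest closed pathway visiting every point exactly
#' once and returning to the start (the travelling-salesman tour over
#' minor-bundle centres). Instances with at most `exact_limit` points
#' are solved exactly by Held--Karp dynamic programming (identical
#' optimum to full permutation enumeration at a fraction of the cost);
#' larger instances -- which arise for cultivars with more than twelve
#' minor bundles, where the original enumeration was truncated after
#' five minutes -- use a nearest-neighbour start with 2-opt improvement
#' until a local optimum or the time budget is reached.
#'
#' @param points 2-column matrix of point coordinates (0 or more rows).
#' @param time_budget heuristic time budget in seconds (default 300,
#'   mirroring the original truncation; tests use much less).
#' @param exact_limit largest instance solved exactly (default 13).
#' @return list with `length` (0 for fewer than 2 points; twice the
#'   pairwise distance for 2) and `tour` (1-based visiting order).
#' @export
shortest_tour_length <- function(points, time_budget = 300,
                                 exact_limit = 13) {
  p <- as.matrix(points)
  n <- nrow(p)
  if (n < 2L) {
    return(list(length = 0, tour = seq_len(n)))
  }
  D <- as.matrix(stats::dist(p))
  if (n == 2L) {
    return(list(length = 2 * D[1, 2], tour = c(1L, 2L)))
  }
  if (n <= exact_limit) {
    .held_karp_cpp(D)
  } else {
    .tsp_heuristic_cpp(D, time_budget)
  }
}
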