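#' The Humphrey 10-2 test-point grid
#'
#' The 10-2 pattern tests 68 locations spaced 2 degrees apart within the
#' central 10 degrees of the visual field. Candidate locations sit at odd
#' eccentricities (+-1, +-3, ..., +-9 degrees) on both axes; the pattern keeps
#' those within a circular cutoff, which leaves exactly 68 points (for
#' example (9, 1) is tested but (9, 3) is not).
#'
#' @return A tibble with one row per location and columns `point_index`
#'   (1-based, row-major: superior rows first, then left to right),
#'   `x_deg` and `y_deg` (degrees of eccentricity; positive x temporal for a
#'   right eye in screen convention, positive y superior).
#' @examples
#' g <- build_grid_10_2()
#' nrow(g) # 68
#' @export
build_grid_10_2 <- function() {
  odd <- seq(-9L, 9L, by = 2L)
  pts <- expand.grid(x_deg = odd, y_deg = odd)
  pts <- pts[pts$x_deg^2 + pts$y_deg^2 <= 82, , drop = FALSE]
  # row-major: y descending, then x ascending
  pts <- pts[order(-pts$y_deg, pts$x_deg), , drop = FALSE]
  stopifnot(nrow(pts) == 68L)
  tibble::tibble(
    point_index = seq_len(nrow(pts)),
    x_deg = as.integer(pts$x_deg),
    y_deg = as.integer(pts$y_deg)
  )
}

# Number of locations on the 10-2 grid; used throughout as the width of
# sensitivity matrices.
N_POINTS <- 68L
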