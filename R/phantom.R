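# Nodule spatial distribution of the anthropomorphic thorax phantom used in
# the observer study: 46 nodules on a (level x depth x side) grid, with 18
# additionally labelled peripheral (within ~2 cm of the chest wall).  The
# printed peripheral request of 5 for (lower, left) exceeds that cell's 4
# nodules; the surplus flag is reassigned to (mid, left), keeping the
# peripheral total at 18.
phantom_grid <- function() {
  tibble(
    level = rep(c("upper", "mid", "lower"), each = 6),
    depth = rep(rep(c("anterior", "posterior", "central"), each = 2), 3),
    side = rep(c("right", "left"), 9),
    n = c(0, 3, 3, 1, 0, 1,
          2, 1, 9, 7, 3, 4,
          2, 0, 3, 2, 3, 2))
}

phantom_peripheral <- function() {
  tibble(level = rep(c("upper", "mid", "lower"), each = 2),
         side = rep(c("right", "left"), 3),
         n_peripheral = c(0, 2, 2, 6, 4, 4))
}

#' Truth fixture emulating the thorax-phantom observer study
#'
#' Builds a synthetic truth table with the study's design: 34 normal and 34
#' abnormal cases, 46 nodules allocated with per-case counts in \{1, 2, 3\}
#' (23 + 10 + 1 cases; mean 1.35, SD 0.54), spatial zones reproducing the
#' phantom's nodule-distribution grid exactly (25 right : 21 left, 8 upper :
#' 26 mid : 12 lower, 8 anterior : 25 posterior : 13 central, 18
#' peripheral), nodule diameters drawn from \{5, 8, 10, 12\} mm and electron
#' densities from \{+100, -630, -800\} HU. Pixel coordinates are placed on a
#' 512 x 512 grid inside boxes consistent with each nodule's side and depth
#' label. The zone grid and per-case count allocation are fixed; only sizes,
#' densities, coordinates and the lesion-to-case assignment depend on
#' `seed`.
#'
#' @param seed Integer seed.
#' @return A [froc_truth()] object.
#' @examples
#' truth <- make_phantom_truth()
#' nrow(truth$lesions)  # 46
#' @export
make_phantom_truth <- function(seed = 1) {
  set.seed(substream_seed(seed, 11))
  grid <- phantom_grid()
  les <- grid[rep(seq_len(nrow(grid)), grid$n), c("level", "depth", "side")]

  # peripheral flags within each (level, side), anterior wall first
  per <- phantom_peripheral()
  les$peripheral <- FALSE
  depth_order <- c(anterior = 1, posterior = 2, central = 3)
  for (r in seq_len(nrow(per))) {
    idx <- which(les$level == per$level[r] & les$side == per$side[r])
    idx <- idx[order(depth_order[les$depth[idx]])]
    les$peripheral[utils::head(idx, per$n_peripheral[r])] <- TRUE
  }

  les$diameter_mm <- sample(c(5, 8, 10, 12), nrow(les), replace = TRUE)
  les$density_hu <- sample(c(100, -630, -800), nrow(les), replace = TRUE)
  xr <- list(right = c(60, 230), left = c(282, 452))
  yr <- list(anterior = c(60, 180), central = c(200, 310),
             posterior = c(330, 450))
  les$x <- round(vapply(les$side, function(s) runif(1, xr[[s]][1],
                                                    xr[[s]][2]), 1))
  les$y <- round(vapply(les$depth, function(d) runif(1, yr[[d]][1],
                                                     yr[[d]][2]), 1))

  # 46 nodules over 34 cases: 23 x 1, 10 x 2, 1 x 3 (mean 1.35, SD 0.54)
  counts <- sample(rep(1:3, c(23, 10, 1)))
  abnormal_cases <- sprintf("A%02d", 1:34)
  les <- les[sample.int(nrow(les)), ]
  les$case <- rep(abnormal_cases, counts)
  les <- les %>%
    group_by(.data$case) %>%
    mutate(lesion = sprintf("L%d", dplyr::row_number())) %>%
    ungroup() %>%
    select("case", "lesion", "x", "y", "diameter_mm", "density_hu",
           "side", "level", "depth", "peripheral") %>%
    arrange(.data$case, .data$lesion)

  froc_truth(
    cases = tibble(case = c(sprintf("N%02d", 1:34), abnormal_cases),
                   abnormal = rep(c(FALSE, TRUE), each = 34)),
    lesions = les)
}
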