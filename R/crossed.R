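#' Collapse a crossed FOM matrix over one factor
#'
#' Averages the per-cell figures of merit over the factor that is *not*
#' under analysis, reader by reader:
#' \eqn{\theta_{i_1 \cdot j} = I_2^{-1} \sum_{i_2} \theta_{i_1 i_2 j}} when
#' keeping factor 1, and symmetrically for factor 2. FOMs - not ratings -
#' are averaged; this is the quantity the single-factor ORH analysis then
#' operates on.
#'
#' @param fom A [fom_matrix()] tibble (columns `factor1`, `factor2`,
#'   `reader`, `fom`).
#' @param keep Which factor to retain as the treatment factor; the other is
#'   averaged out.
#' @return A tibble with columns `treatment`, `reader`, `fom`.
#' @export
average_over_factor <- function(fom, keep = c("factor1", "factor2")) {
  keep <- match.arg(keep)
  fom <- as_tibble(fom)
  stopifnot(all(c("factor1", "factor2", "reader", "fom") %in% names(fom)))
  fom %>%
    group_by(treatment = .data[[keep]], .data$reader) %>%
    summarise(fom = mean(.data$fom), .groups = "drop")
}

#' Number of pairwise treatment comparisons
#'
#' With `I` treatment levels there are `I * (I - 1) / 2` distinct pairs.
#'
#' @param I Number of treatment levels (non-negative integer).
#' @return Integer pair count.
#' @examples
#' n_pairwise(4)  # 6
#' n_pairwise(8)  # 28
#' @export
n_pairwise <- function(I) {
  stopifnot(I >= 0)
  I * (I - 1) / 2
}

#' Crossed-modality FROC analysis
#'
#' The full two-factor procedure for a study whose imaging condition is
#' defined by two fully crossed factors (e.g. mAs x reconstruction method).
#' Two sequential single-factor random-reader fixed-case ORH analyses are
#' run: the factor-1 analysis on FOMs averaged over factor 2, and the
#' factor-2 analysis on FOMs averaged over factor 1. Because two analyses
#' interrogate the same data, each is tested at the Bonferroni-corrected
#' threshold `overall_alpha / 2` (0.025 by default), conservatively holding
#' the family-wise type-I error at `overall_alpha`. Within each analysis the
#' protected pairwise rule applies: a pair is significant only when both the
#' overall F-test and the pairwise t-test fall below the corrected
#' threshold.
#'
#' @param ds A [froc_data()] object, or a precomputed [fom_matrix()] tibble.
#' @param fom FOM type, `"wafroc"` or `"roc"` (ignored when `ds` is already
#'   a FOM table).
#' @param overall_alpha Family-wise significance level, split equally across
#'   the `n_analyses = 2` analyses.
#' @param tie Tie value for the [psi()] kernel.
#' @return A `crossed_result`: list with `orh_result`s `factor1_analysis`
#'   and `factor2_analysis`, plus `fom` (the cell-level FOM table),
#'   `overall_alpha`, `bonferroni_alpha` and `n_analyses`.
#' @examples
#' cfg <- sim_config(I1 = 2, I2 = 2, J = 4, K1 = 10, K2 = 10, seed = 7)
#' res <- crossed_modality_analysis(simulate_froc(cfg))
#' glance(res)
#' @export
crossed_modality_analysis <- function(ds, fom = c("wafroc", "roc"),
                                      overall_alpha = 0.05, tie = 0.5) {
  fom <- match.arg(fom)
  if (inherits(ds, "froc_data")) {
    fm <- fom_matrix(ds, fom = fom, tie = tie)
  } else {
    fm <- as_tibble(ds)
    stopifnot(all(c("factor1", "factor2", "reader", "fom") %in% names(fm)))
  }
  if (dplyr::n_distinct(fm$factor1) < 2 || dplyr::n_distinct(fm$factor2) < 2) {
    abort("crossed analysis needs >= 2 levels of both factors")
  }
  alpha <- overall_alpha / 2
  a1 <- rrfc_analysis(average_over_factor(fm, "factor1"), alpha = alpha)
  a2 <- rrfc_analysis(average_over_factor(fm, "factor2"), alpha = alpha)
  structure(list(factor1_analysis = a1, factor2_analysis = a2, fom = fm,
                 fom_type = attr(fm, "fom_type") %||% fom,
                 overall_alpha = overall_alpha, bonferroni_alpha = alpha,
                 n_analyses = 2L),
            class = "crossed_result")
}

#' @export
print.crossed_result <- function(x, ...) {
  cat("<crossed_result> crossed-modality ", x$fom_type,
      " analysis (RRFC), Bonferroni threshold ",
      format(x$bonferroni_alpha), "\n", sep = "")
  for (nm in c("factor1_analysis", "factor2_analysis")) {
    a <- x[[nm]]
    cat(sprintf("  %s: F(%g, %g) = %.4g, p = %.4g; %d of %d pairs significant\n",
                sub("_analysis", "", nm), a$ndf, a$ddf, a$F, a$p,
                sum(a$pairwise$significant), nrow(a$pairwise)))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.crossed_result <- function(x, ...) {
  bind_rows(
    mutate(x$factor1_analysis$pairwise, analysis = "factor1", .before = 1),
    mutate(x$factor2_analysis$pairwise, analysis = "factor2", .before = 1))
}

#' @exportS3Method generics::glance
glance.crossed_result <- function(x, ...) {
  bind_rows(
    mutate(glance(x$factor1_analysis), analysis = "factor1"),
    mutate(glance(x$factor2_analysis), analysis = "factor2")) %>%
    mutate(bonferroni_alpha = x$bonferroni_alpha)
}

#' Welch's t-test between two reader groups
#'
#' Compares mean performance between two professional groups of readers
#' (e.g. radiologists vs radiographers). Each reader is summarised by the
#' unweighted mean of their figures of merit over all design cells (the
#' design is balanced, so every cell counts equally); the two groups are
#' compared with Welch's unequal-variance t-test and Satterthwaite degrees
#' of freedom.
#'
#' @param fom A [fom_matrix()] tibble.
#' @param groups Named character vector (or factor) mapping each reader id
#'   to a group label; exactly two groups, each with at least two readers.
#' @param conf.level Confidence level of the reported difference CI.
#' @return One-row tibble: `group1`, `group2`, `estimate` (mean difference
#'   group1 - group2), `statistic`, `parameter` (df), `p.value`, `conf.low`,
#'   `conf.high`.
#' @export
reader_group_ttest <- function(fom, groups, conf.level = 0.95) {
  fom <- as_tibble(fom)
  stopifnot(all(c("reader", "fom") %in% names(fom)))
  per_reader <- fom %>%
    group_by(.data$reader) %>%
    summarise(fom = mean(.data$fom), .groups = "drop")
  if (is.null(names(groups))) {
    abort("`groups` must be named by reader id")
  }
  per_reader$group <- as.character(groups[per_reader$reader])
  if (anyNA(per_reader$group)) {
    abort("`groups` is missing labels for some readers")
  }
  gl <- sort(unique(per_reader$group))
  if (length(gl) != 2) abort("exactly two reader groups are required")
  n_by <- table(per_reader$group)
  if (any(n_by < 2)) abort("each reader group needs at least 2 readers")
  x <- per_reader$fom[per_reader$group == gl[1]]
  y <- per_reader$fom[per_reader$group == gl[2]]
  tt <- t.test(x, y, var.equal = FALSE, conf.level = conf.level)
  tibble(group1 = gl[1], group2 = gl[2],
         estimate = unname(diff(rev(tt$estimate))),
         statistic = unname(tt$statistic), parameter = unname(tt$parameter),
         p.value = tt$p.value,
         conf.low = tt$conf.int[1], conf.high = tt$conf.int[2])
}
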