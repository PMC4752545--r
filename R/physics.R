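#' Contrast-to-noise ratio
#'
#' CNR of a nodule against a uniform background region:
#' \deqn{CNR = |\mu_{nodule} - \mu_{background}| / \sigma_{background}.}
#' The numerator is the contrast; with a fixed reconstruction kernel the HU
#' of nodule and background are stable, so the noise term drives CNR
#' differences between acquisitions. Vectorised; also accepts a measurement
#' data frame, to which it adds `contrast` and `cnr` columns.
#'
#' @param nodule_mean Mean pixel value inside the nodule ROI (HU), or a data
#'   frame with columns `nodule_mean`, `background_mean`, `background_sd`.
#' @param background_mean,background_sd Mean and SD of the background ROI.
#' @return Numeric CNR values, or the input tibble with `contrast` and `cnr`
#'   columns appended.
#' @examples
#' cnr(500, -800, 100)  # 13
#' @export
cnr <- function(nodule_mean, background_mean = NULL, background_sd = NULL) {
  if (is.data.frame(nodule_mean)) {
    d <- as_tibble(nodule_mean)
    stopifnot(all(c("nodule_mean", "background_mean", "background_sd")
                  %in% names(d)))
    return(mutate(d,
                  contrast = abs(.data$nodule_mean - .data$background_mean),
                  cnr = cnr(.data$nodule_mean, .data$background_mean,
                            .data$background_sd)))
  }
  if (any(background_sd <= 0)) abort("background_sd must be positive")
  abs(nodule_mean - background_mean) / background_sd
}

#' Two-factor linear trend of CNR
#'
#' Ordinary least squares of CNR on the tube current-time product (mAs,
#' continuous) and the reconstruction method (indicator), with coefficient
#' t-tests. Answers whether exposure and reconstruction each shift image
#' quality, and by how much per mAs.
#'
#' @param measurements Data frame with columns `nodule_mean`,
#'   `background_mean`, `background_sd` (or a precomputed `cnr` column),
#'   `mas` (numeric) and `reconstruction` (two-level factor/character).
#' @return A `cnr_trend` object wrapping the [stats::lm] fit; `tidy()` and
#'   `glance()` give coefficient and fit summaries.
#' @export
cnr_trend <- function(measurements) {
  d <- as_tibble(measurements)
  stopifnot(all(c("mas", "reconstruction") %in% names(d)))
  if (!"cnr" %in% names(d)) d <- cnr(d)
  if (nrow(d) < 3) abort("need at least 3 measurements")
  d$reconstruction <- factor(d$reconstruction)
  if (dplyr::n_distinct(d$mas) < 2 || nlevels(d$reconstruction) < 2) {
    abort("rank-deficient design: both mAs and reconstruction must vary")
  }
  fit <- lm(cnr ~ mas + reconstruction, data = d)
  structure(list(fit = fit, n = nrow(d)), class = "cnr_trend")
}

#' @export
print.cnr_trend <- function(x, ...) {
  cat("<cnr_trend> OLS of CNR on mAs + reconstruction,", x$n, "measurements\n")
  print(summary(x$fit)$coefficients, digits = 4)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cnr_trend <- function(x, conf.int = FALSE, conf.level = 0.95, ...) {
  co <- summary(x$fit)$coefficients
  out <- tibble(term = rownames(co), estimate = co[, 1], std.error = co[, 2],
                statistic = co[, 3], p.value = co[, 4])
  if (conf.int) {
    ci <- stats::confint(x$fit, level = conf.level)
    out$conf.low <- ci[, 1]; out$conf.high <- ci[, 2]
  }
  out
}

#' @exportS3Method generics::glance
glance.cnr_trend <- function(x, ...) {
  s <- summary(x$fit)
  tibble(r.squared = s$r.squared, sigma = s$sigma,
         statistic = unname(s$fstatistic[1]),
         df = unname(s$fstatistic[2]), df.residual = unname(s$fstatistic[3]),
         nobs = x$n)
}

#' ICRP 103 tissue-weighting factors
#'
#' The tissue-weighting table used by [effective_dose()]: named weights for
#' the explicitly weighted organs plus a single pooled `remainder` term
#' (w = 0.12) evaluated as the mean dose over the 13 remainder tissues.
#' Weights sum to 1.
#'
#' @return Tibble with columns `tissue` and `w`; the remainder tissue names
#'   are attached as attribute `remainder_tissues`.
#' @export
icrp103_weights <- function() {
  out <- tibble(
    tissue = c("red_bone_marrow", "colon", "lung", "stomach", "breast",
               "remainder", "gonads", "bladder", "oesophagus", "liver",
               "thyroid", "bone_surface", "brain", "salivary_glands", "skin"),
    w = c(rep(0.12, 6), 0.08, rep(0.04, 4), rep(0.01, 4)))
  attr(out, "remainder_tissues") <- c(
    "adrenals", "extrathoracic_region", "gall_bladder", "heart", "kidneys",
    "lymphatic_nodes", "muscle", "oral_mucosa", "pancreas",
    "prostate_uterus", "small_intestine", "spleen", "thymus")
  out
}

#' Effective dose from organ doses
#'
#' ICRP 103 effective dose \eqn{E = \sum_T w_T H_T} in mSv, with photon
#' radiation weighting 1 so each equivalent organ dose \eqn{H_T} equals the
#' absorbed dose in mGy. Doses supplied for individual remainder tissues are
#' pooled by their mean and weighted by the single remainder factor; a dose
#' named `remainder` is used directly. Organs with no supplied dose
#' contribute zero (a partial-body exposure); unknown organ names are an
#' error.
#'
#' @param doses Data frame with columns `organ` and `dose_mgy`, or a named
#'   numeric vector of absorbed doses in mGy.
#' @param weights Tissue-weighting table as from [icrp103_weights()]; must
#'   sum to 1 (tolerance 1e-9).
#' @return Effective dose in mSv (scalar).
#' @examples
#' effective_dose(c(lung = 1))             # 0.12
#' w <- icrp103_weights()
#' effective_dose(setNames(rep(2, nrow(w)), w$tissue))  # 2
#' @export
effective_dose <- function(doses, weights = icrp103_weights()) {
  if (is.data.frame(doses)) {
    stopifnot(all(c("organ", "dose_mgy") %in% names(doses)))
    dv <- stats::setNames(as.numeric(doses$dose_mgy),
                          as.character(doses$organ))
  } else {
    stopifnot(is.numeric(doses), !is.null(names(doses)))
    dv <- doses
  }
  if (abs(sum(weights$w) - 1) > 1e-9) {
    abort("tissue weights must sum to 1")
  }
  if (any(dv < 0)) abort("organ doses must be non-negative")
  remainder <- attr(weights, "remainder_tissues") %||% character()
  known <- c(weights$tissue, remainder)
  unknown <- setdiff(names(dv), known)
  if (length(unknown) > 0) {
    abort(paste("unknown organ name(s):", paste(unknown, collapse = ", ")))
  }
  in_rem <- names(dv) %in% remainder
  rem_dose <- if (any(in_rem)) mean(dv[in_rem]) else 0
  main <- dv[!in_rem]
  if ("remainder" %in% names(main)) {
    if (any(in_rem)) {
      abort("supply either a pooled 'remainder' dose or individual remainder tissues, not both")
    }
    rem_dose <- main[["remainder"]]
    main <- main[names(main) != "remainder"]
  }
  full <- stats::setNames(rep(0, nrow(weights)), weights$tissue)
  full[names(main)] <- main
  full["remainder"] <- rem_dose
  sum(weights$w * full)
}
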