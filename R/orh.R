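#' Obuchowski-Rockette/Hillis analysis of a treatment-by-reader FOM matrix
#'
#' `rrfc_analysis()` performs the random-reader fixed-case (RRFC)
#' generalization: readers are a random sample, the case set is fixed (the
#' appropriate model when the cases come from a single physical phantom).
#' With \eqn{I} treatments and \eqn{J} readers,
#' \deqn{F = MS(T) / MS(TR), \quad F \sim F_{I-1,\,(I-1)(J-1)}}
#' where \eqn{MS(T)} is the treatment mean square and \eqn{MS(TR)} the
#' treatment-by-reader interaction mean square of the two-way FOM table.
#' Pairwise treatment differences use
#' \eqn{t = (\bar\theta_{i\cdot} - \bar\theta_{i'\cdot}) /
#' \sqrt{2\,MS(TR)/J}} on \eqn{(I-1)(J-1)} df, with matching two-sided
#' confidence intervals, so a CI excludes zero exactly when the pairwise
#' p-value is below `alpha`.
#'
#' `rrrc_analysis()` is the random-reader random-case generalization with the
#' Hillis denominator \eqn{MS(TR) + J \max(Cov_2 - Cov_3, 0)} and Hillis
#' denominator degrees of freedom; it needs the jackknife covariance
#' components from [jackknife_covariances()]. When `cov2 == cov3` it reduces
#' exactly to the RRFC analysis.
#'
#' A pairwise difference is flagged `significant` only under the protected
#' rule: both the overall F-test p-value and the pairwise p-value must be
#' below `alpha` (see [protected_pairwise()]).
#'
#' @param fom Either an `I x J` numeric matrix (treatments in rows, readers
#'   in columns) or a data frame with columns `treatment`, `reader`, `fom`.
#' @param alpha Significance threshold for the protected pairwise flags and
#'   the CI level (`1 - alpha`).
#' @param cov Covariance components from [jackknife_covariances()] (for
#'   `rrrc_analysis`).
#' @return An `orh_result`: a list with elements `analysis`, `levels`
#'   (treatment means), `F`, `ndf`, `ddf`, `p`, `ms_t`, `ms_tr`, `cov`,
#'   `pairwise` (tibble with protected `significant` flags) and `alpha`.
#'   [tidy()] returns the pairwise table, [glance()] the overall test.
#' @examples
#' th <- matrix(c(0.8, 0.9, 0.6, 0.75), nrow = 2, byrow = TRUE,
#'              dimnames = list(c("A", "B"), c("r1", "r2")))
#' rrfc_analysis(th)  # F = 49 on (1, 1) df
#' @export
rrfc_analysis <- function(fom, alpha = 0.05) {
  m <- as_fom_table(fom)
  orh_core(m, denom = NULL, cov = NULL, analysis = "rrfc", alpha = alpha)
}

#' @rdname rrfc_analysis
#' @export
rrrc_analysis <- function(fom, cov, alpha = 0.05) {
  m <- as_fom_table(fom)
  stopifnot(is.list(cov), all(c("cov2", "cov3") %in% names(cov)))
  orh_core(m, denom = cov, cov = cov, analysis = "rrrc", alpha = alpha)
}

as_fom_table <- function(fom) {
  if (is.matrix(fom)) {
    if (is.null(rownames(fom))) {
      rownames(fom) <- paste0("T", seq_len(nrow(fom)))
    }
    return(fom)
  }
  fom <- as_tibble(fom)
  stopifnot(all(c("treatment", "reader", "fom") %in% names(fom)))
  wide <- tidyr::pivot_wider(fom[, c("treatment", "reader", "fom")],
                             names_from = "reader", values_from = "fom")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- as.character(wide$treatment)
  if (anyNA(m)) abort("incomplete design: missing (treatment, reader) cells")
  m
}

orh_core <- function(m, denom, cov, analysis, alpha) {
  I <- nrow(m); J <- ncol(m)
  if (I < 2 || J < 2) abort("need at least 2 treatments and 2 readers")
  if (!all(is.finite(m))) abort("non-finite figures of merit")
  stopifnot(alpha >= 0, alpha <= 1)
  ti <- rowMeans(m); tj <- colMeans(m); tt <- mean(m)
  ms_t <- J / (I - 1) * sum((ti - tt)^2)
  resid <- m - outer(ti, rep(1, J)) - outer(rep(1, I), tj) + tt
  ms_tr <- sum(resid^2) / ((I - 1) * (J - 1))
  if (ms_tr < .Machine$double.eps^0.75) {
    abort("degenerate design: treatment-by-reader mean square is ~0, F undefined")
  }
  if (analysis == "rrfc") {
    den <- ms_tr
    ddf <- (I - 1) * (J - 1)
  } else {
    den <- ms_tr + J * max(denom$cov2 - denom$cov3, 0)
    ddf <- den^2 / (ms_tr^2 / ((I - 1) * (J - 1)))
  }
  Fstat <- ms_t / den
  ndf <- I - 1
  p <- pf(Fstat, ndf, ddf, lower.tail = FALSE)

  pairs <- utils::combn(seq_len(I), 2)
  se <- sqrt(2 * den / J)
  est <- ti[pairs[1, ]] - ti[pairs[2, ]]
  tval <- est / se
  pp <- 2 * pt(abs(tval), ddf, lower.tail = FALSE)
  hw <- qt(1 - alpha / 2, ddf) * se
  pairwise <- tibble(
    treatment1 = rownames(m)[pairs[1, ]],
    treatment2 = rownames(m)[pairs[2, ]],
    estimate = unname(est),
    conf.low = unname(est - hw), conf.high = unname(est + hw),
    statistic = unname(tval), p.value = unname(pp),
    significant = p < alpha & pp < alpha)
  structure(list(analysis = analysis,
                 levels = tibble(treatment = rownames(m),
                                 fom = unname(ti)),
                 F = Fstat, ndf = ndf, ddf = ddf, p = p,
                 ms_t = ms_t, ms_tr = ms_tr, cov = cov,
                 pairwise = pairwise, alpha = alpha),
            class = "orh_result")
}

#' Protected pairwise significance
#'
#' Re-applies the protected significance rule at a (possibly new) threshold:
#' a treatment pair is declared significant only when the overall F-test
#' p-value and the pairwise t-test p-value are both below `alpha`. The rule
#' guards the pairwise comparisons behind the omnibus test.
#'
#' @param result An `orh_result`.
#' @param alpha Threshold; defaults to the one stored in `result`.
#' @return The pairwise tibble with the `significant` flag recomputed.
#' @export
protected_pairwise <- function(result, alpha = result$alpha) {
  stopifnot(inherits(result, "orh_result"))
  mutate(result$pairwise,
         significant = result$p < alpha & .data$p.value < alpha)
}

#' Jackknife covariance components
#'
#' Estimates the Obuchowski-Rockette covariance structure from
#' leave-one-case-out FOMs. For cells \eqn{c = (i, j)} and \eqn{c' = (i',
#' j')} sharing one case set of size \eqn{K},
#' \deqn{\widehat{Cov}(c, c') = \frac{K-1}{K} \sum_{k=1}^{K}
#'   (\theta_{c(k)} - \bar\theta_{c(\cdot)})
#'   (\theta_{c'(k)} - \bar\theta_{c'(\cdot)}).}
#' `cov1` averages same-reader different-treatment pairs, `cov2`
#' same-treatment different-reader pairs, `cov3` pairs differing in both,
#' and `var` the diagonal. Estimates may be negative; truncation is applied
#' only inside the Hillis denominator of [rrrc_analysis()].
#'
#' @param jk A data frame with columns `treatment`, `reader`, `case` and
#'   `theta_loo`, e.g. [jackknife_foms()] output with the two design factors
#'   united into `treatment` (or one factor averaged out).
#' @return A list with `cov1`, `cov2`, `cov3`, `var` and the full
#'   cell-by-cell covariance `matrix`.
#' @export
jackknife_covariances <- function(jk) {
  jk <- as_tibble(jk)
  stopifnot(all(c("treatment", "reader", "case", "theta_loo") %in% names(jk)))
  wide <- tidyr::pivot_wider(
    jk[, c("treatment", "reader", "case", "theta_loo")],
    names_from = c("treatment", "reader"), values_from = "theta_loo",
    names_sep = "\r")
  x <- as.matrix(wide[, -1, drop = FALSE])
  if (anyNA(x)) abort("mismatched case sets across design cells")
  K <- nrow(x)
  xc <- scale(x, center = TRUE, scale = FALSE)
  cc <- (K - 1) / K * crossprod(xc)
  ids <- do.call(rbind, strsplit(colnames(x), "\r", fixed = TRUE))
  same_t <- outer(ids[, 1], ids[, 1], "==")
  same_r <- outer(ids[, 2], ids[, 2], "==")
  diag_m <- diag(nrow(cc)) == 1
  pick <- function(mask) if (any(mask)) mean(cc[mask]) else NA_real_
  list(cov1 = pick(!same_t & same_r & !diag_m),
       cov2 = pick(same_t & !same_r & !diag_m),
       cov3 = pick(!same_t & !same_r & !diag_m),
       var = mean(diag(cc)),
       matrix = cc)
}

#' @export
print.orh_result <- function(x, ...) {
  cat("<orh_result> ", toupper(x$analysis), " analysis of ",
      nrow(x$levels), " treatments x readers\n", sep = "")
  cat(sprintf("  F(%g, %g) = %.4g, p = %.4g\n", x$ndf, round(x$ddf, 2),
              x$F, x$p))
  print(as.data.frame(x$pairwise), digits = 4)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.orh_result <- function(x, ...) x$pairwise

#' @exportS3Method generics::glance
glance.orh_result <- function(x, ...) {
  tibble(statistic = x$F, ndf = x$ndf, ddf = x$ddf, p.value = x$p,
         ms_t = x$ms_t, ms_tr = x$ms_tr, analysis = x$analysis,
         alpha = x$alpha)
}
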