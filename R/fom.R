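#' Empirical probability kernel
#'
#' The kernel of the empirical probability that one rating exceeds another:
#' 1 when `a > b`, 0.5 (the `tie` value) when `a == b`, 0 when `a < b`.
#' Ratings may be the unmarked sentinel `-Inf`; two unmarked entities compare
#' as a tie, so an observer who marks nothing scores 0.5.
#'
#' @param a,b Numeric rating vectors (recycled).
#' @param tie Value awarded to ties; 0.5 by default.
#' @return Numeric vector of kernel scores.
#' @export
psi <- function(a, b, tie = 0.5) {
  (a > b) + tie * (a == b)
}

#' Figures of merit for one design cell
#'
#' `wafroc_fom()` computes the equally weighted JAFROC (wAFROC) figure of
#' merit: the weighted empirical probability that a lesion rating exceeds the
#' highest non-lesion rating on a normal case,
#' \deqn{\theta = \frac{1}{K_1 K_2} \sum_{n=1}^{K_1} \sum_{a=1}^{K_2}
#'       \sum_{l \in a} W_{al}\, \psi(LL_{al}, FP_n),}
#' where \eqn{FP_n} is the highest NL rating on normal case \eqn{n} (`-Inf`
#' if unmarked) and the per-case weights \eqn{W_{al}} sum to one, giving each
#' abnormal case equal importance. Only normal cases generate false
#' positives; NL marks on abnormal cases do not enter the wAFROC.
#'
#' `inferred_roc_fom()` is the empirical ROC area (Wilcoxon statistic) of the
#' inferred ROC ratings: each case is represented by its single highest
#' rating over all of its marks, NL or LL.
#'
#' @param ll Numeric vector of lesion (LL) ratings, one per true lesion,
#'   `-Inf` for unmarked lesions.
#' @param fp Numeric vector of per-normal-case highest NL ratings, `-Inf`
#'   for unmarked normal cases.
#' @param weights Lesion weights aligned with `ll`; per-case weights must sum
#'   to 1 so that `sum(weights)` equals the number of abnormal cases.
#' @param h_abnormal,h_normal Highest rating per abnormal / normal case.
#' @param tie Tie value passed to [psi()].
#' @return The figure of merit, a number in \[0, 1\].
#' @examples
#' # two normal cases (highest NL 3, unmarked), two one-lesion abnormal
#' # cases (LL 5, unmarked):
#' wafroc_fom(ll = c(5, -Inf), fp = c(3, -Inf), weights = c(1, 1))  # 0.625
#' @export
wafroc_fom <- function(ll, fp, weights, tie = 0.5) {
  if (length(fp) < 1 || length(ll) < 1) {
    abort("undefined FOM: need at least one normal and one abnormal case")
  }
  stopifnot(length(weights) == length(ll))
  k2 <- sum(weights)
  sum(weights * colMeans(outer(fp, ll, function(b, a) psi(a, b, tie)))) / k2
}

#' @rdname wafroc_fom
#' @export
inferred_roc_fom <- function(h_abnormal, h_normal, tie = 0.5) {
  if (length(h_normal) < 1 || length(h_abnormal) < 1) {
    abort("undefined FOM: need at least one normal and one abnormal case")
  }
  mean(psi(rep(h_abnormal, times = length(h_normal)),
           rep(h_normal, each = length(h_abnormal)), tie))
}

# Per-cell rating structures. Returns, for the marks of one design cell:
# fp (K1), ll (L), h_norm (K1), h_abn (K2), all filled with the unmarked
# sentinel where no mark exists.
cell_ratings <- function(mk, env) {
  fp <- rep(UNMARKED, env$K1)
  ll <- rep(UNMARKED, env$L)
  h_abn <- rep(UNMARKED, env$K2)
  if (nrow(mk) > 0) {
    nl_n <- mk$type == "NL" & mk$case %in% env$normal_cases
    if (any(nl_n)) {
      mx <- tapply(mk$rating[nl_n],
                   factor(mk$case[nl_n], levels = env$normal_cases), max)
      fp[!is.na(mx)] <- mx[!is.na(mx)]
    }
    is_ll <- mk$type == "LL"
    if (any(is_ll)) {
      idx <- match(paste(mk$case[is_ll], mk$lesion[is_ll]), env$lesion_key)
      ll[idx] <- pmax(ll[idx], mk$rating[is_ll])
    }
    on_abn <- mk$case %in% env$abnormal_cases
    if (any(on_abn)) {
      mx <- tapply(mk$rating[on_abn],
                   factor(mk$case[on_abn], levels = env$abnormal_cases), max)
      h_abn[!is.na(mx)] <- mx[!is.na(mx)]
    }
  }
  list(fp = fp, ll = ll, h_norm = fp, h_abn = h_abn)
}

design_env <- function(ds) {
  normal_cases <- ds$truth$cases$case[!ds$truth$cases$abnormal]
  abnormal_cases <- ds$truth$cases$case[ds$truth$cases$abnormal]
  les <- ds$truth$lesions
  list(normal_cases = normal_cases, abnormal_cases = abnormal_cases,
       K1 = length(normal_cases), K2 = length(abnormal_cases),
       L = nrow(les), lesion_key = paste(les$case, les$lesion),
       lesion_case = match(les$case, abnormal_cases), weights = les$weight)
}

cell_index <- function(ds) {
  i1 <- match(ds$marks$factor1, ds$factor1_levels)
  i2 <- match(ds$marks$factor2, ds$factor2_levels)
  j <- match(ds$marks$reader, ds$readers)
  n1 <- length(ds$factor1_levels); n2 <- length(ds$factor2_levels)
  nj <- length(ds$readers)
  idx <- i1 + n1 * (i2 - 1) + n1 * n2 * (j - 1)
  grid <- tidyr::expand_grid(reader = ds$readers, factor2 = ds$factor2_levels,
                             factor1 = ds$factor1_levels) %>%
    select("factor1", "factor2", "reader")
  list(rows = split(seq_len(nrow(ds$marks)),
                    factor(idx, levels = seq_len(n1 * n2 * nj))),
       grid = grid)
}

#' Figure-of-merit matrix over all design cells
#'
#' Computes the figure of merit independently for every
#' (factor1, factor2, reader) cell of a crossed-factor FROC dataset.
#'
#' @param ds A [froc_data()] object with at least one normal and one abnormal
#'   case.
#' @param fom `"wafroc"` (weighted JAFROC, default) or `"roc"`
#'   (highest-rating inferred ROC).
#' @param tie Tie value for the [psi()] kernel.
#' @return A tibble of class `crossfroc_fom` with columns `factor1`,
#'   `factor2`, `reader` and `fom`, carrying the FOM type as attribute
#'   `fom_type`.
#' @seealso [crossed_modality_analysis()], [jackknife_foms()]
#' @export
fom_matrix <- function(ds, fom = c("wafroc", "roc"), tie = 0.5) {
  fom <- match.arg(fom)
  stopifnot(inherits(ds, "froc_data"))
  env <- design_env(ds)
  ci <- cell_index(ds)
  vals <- vapply(ci$rows, function(r) {
    cr <- cell_ratings(ds$marks[r, ], env)
    if (fom == "wafroc") {
      wafroc_fom(cr$ll, cr$fp, env$weights, tie)
    } else {
      inferred_roc_fom(cr$h_abn, cr$h_norm, tie)
    }
  }, numeric(1))
  out <- mutate(ci$grid, fom = unname(vals))
  class(out) <- c("crossfroc_fom", class(out))
  attr(out, "fom_type") <- fom
  out
}

#' Jackknife figures of merit and pseudovalues
#'
#' Leave-one-case-out resampling of the figure of merit within every design
#' cell. For cell FOM \eqn{\theta} and deleted-case FOM \eqn{\theta_{(k)}}
#' the pseudovalue is \eqn{Y_k = K\theta - (K-1)\theta_{(k)}} with
#' \eqn{K = K_1 + K_2} the total number of cases. Pseudovalues are linear in
#' \eqn{\theta}, so averaging pseudovalues over a design factor is identical
#' to jackknifing the factor-averaged FOM; the jackknife covariances needed
#' for random-case analyses come from [jackknife_covariances()].
#'
#' @inheritParams fom_matrix
#' @return A tibble with columns `factor1`, `factor2`, `reader`, `case`,
#'   `theta_loo` (leave-one-out FOM) and `pseudovalue`; the full-data FOMs
#'   are attached as attribute `theta` (a [fom_matrix()] tibble).
#' @export
jackknife_foms <- function(ds, fom = c("wafroc", "roc"), tie = 0.5) {
  fom <- match.arg(fom)
  stopifnot(inherits(ds, "froc_data"))
  env <- design_env(ds)
  if (env$K1 < 2 || env$K2 < 2) {
    abort("undefined FOM under deletion: need >= 2 normal and abnormal cases")
  }
  K <- env$K1 + env$K2
  cases <- c(env$normal_cases, env$abnormal_cases)
  ci <- cell_index(ds)
  res <- purrr::map2(ci$rows, seq_along(ci$rows), function(r, g) {
    cr <- cell_ratings(ds$marks[r, ], env)
    if (fom == "wafroc") {
      s <- env$weights * outer(cr$ll, cr$fp, psi, tie = tie)  # L x K1
      tot <- sum(s)
      theta <- tot / (env$K1 * env$K2)
      loo_n <- (tot - colSums(s)) / ((env$K1 - 1) * env$K2)
      by_case <- rowsum(rowSums(s), group = env$lesion_case)[, 1]
      loo_a <- (tot - by_case) / (env$K1 * (env$K2 - 1))
    } else {
      p <- outer(cr$h_abn, cr$h_norm, psi, tie = tie)  # K2 x K1
      tot <- sum(p)
      theta <- tot / (env$K1 * env$K2)
      loo_n <- (tot - colSums(p)) / ((env$K1 - 1) * env$K2)
      loo_a <- (tot - rowSums(p)) / (env$K1 * (env$K2 - 1))
    }
    loo <- c(loo_n, loo_a)
    tibble(case = cases, theta_loo = unname(loo),
           pseudovalue = K * theta - (K - 1) * unname(loo), theta = theta)
  })
  grid <- ci$grid[rep(seq_len(nrow(ci$grid)), each = K), ]
  out <- dplyr::bind_cols(grid, bind_rows(res))
  theta_tbl <- mutate(ci$grid,
                      fom = unname(purrr::map_dbl(res, ~ .x$theta[1])))
  class(theta_tbl) <- c("crossfroc_fom", class(theta_tbl))
  attr(theta_tbl, "fom_type") <- fom
  out <- select(out, -"theta")
  attr(out, "theta") <- theta_tbl
  attr(out, "K") <- K
  out
}
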