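fom_tbl <- function(values, I1 = 2, I2 = 2, J = 2) {
  d <- expand.grid(factor1 = as.character(seq_len(I1)),
                   factor2 = as.character(seq_len(I2)),
                   reader = paste0("R", seq_len(J)),
                   stringsAsFactors = FALSE)
  d$fom <- values
  d
}

test_that("factor averaging is the reader-wise mean over the other factor", {
  d <- fom_tbl(c(0.8, 0.8, 0.9, 0.9, 0.8, 0.8, 0.9, 0.9), J = 2)
  a1 <- average_over_factor(d, "factor1")
  expect_equal(sort(unique(a1$fom)), 0.85)
  const <- average_over_factor(fom_tbl(rep(0.7, 8)), "factor2")
  expect_equal(const$fom, rep(0.7, 4))
  # collapsing either way then averaging gives the same reader-wise grand mean
  d2 <- fom_tbl(runif(8, 0.5, 1))
  g1 <- dplyr::summarise(dplyr::group_by(average_over_factor(d2, "factor1"),
                                         reader), m = mean(fom))
  g2 <- dplyr::summarise(dplyr::group_by(average_over_factor(d2, "factor2"),
                                         reader), m = mean(fom))
  expect_equal(g1$m, g2$m)
})

test_that("pair counts match explicit enumeration", {
  for (I in 1:9) {
    expected <- if (I < 2) 0 else ncol(utils::combn(I, 2))
    expect_equal(n_pairwise(I), expected)
  }
  expect_equal(n_pairwise(8), 28)
  expect_equal(n_pairwise(4), 6)
  expect_equal(n_pairwise(2), 1)
})

test_that("the crossed procedure runs both analyses at alpha / 2", {
  ds <- simulate_froc(sim_config(I1 = 4, I2 = 2, J = 11, K1 = 6, K2 = 6,
                                 seed = 8))
  res <- crossed_modality_analysis(ds, overall_alpha = 0.05)
  expect_equal(res$bonferroni_alpha, 0.025)
  expect_equal(res$n_analyses, 2L)
  expect_equal(res$factor1_analysis$alpha, 0.025)
  expect_equal(nrow(res$factor1_analysis$pairwise), 6)
  expect_equal(nrow(res$factor2_analysis$pairwise), 1)
  expect_equal(c(res$factor1_analysis$ndf, res$factor1_analysis$ddf),
               c(3, 30))
  expect_equal(c(res$factor2_analysis$ndf, res$factor2_analysis$ddf),
               c(1, 10))
})

test_that("collapsing a duplicated factor reproduces single-factor RRFC", {
  # factor 2 levels are exact copies, so averaging over factor 2 changes
  # nothing and the factor-1 analysis must equal plain RRFC on one level
  set.seed(31)
  half <- expand.grid(factor1 = c("1", "2", "3"), reader = paste0("R", 1:5),
                      stringsAsFactors = FALSE)
  half$fom <- runif(nrow(half), 0.6, 0.95)
  full <- rbind(transform(half, factor2 = "a"),
                transform(half, factor2 = "b"))
  collapsed <- rrfc_analysis(average_over_factor(full, "factor1"),
                             alpha = 0.025)
  single <- rrfc_analysis(
    dplyr::rename(half, treatment = factor1), alpha = 0.025)
  expect_equal(collapsed$F, single$F)
  expect_equal(collapsed$p, single$p)
  expect_equal(collapsed$pairwise$estimate, single$pairwise$estimate)
})

test_that("pseudovalue averaging commutes with factor collapsing", {
  ds <- simulate_froc(sim_config(I1 = 2, I2 = 2, J = 2, K1 = 5, K2 = 5,
                                 seed = 12))
  jk <- jackknife_foms(ds)
  K <- attr(jk, "K")
  th <- attr(jk, "theta")
  # average the per-cell jackknife quantities over factor 2 ...
  avg <- dplyr::summarise(
    dplyr::group_by(jk, factor1, reader, case),
    mean_pseudo = mean(pseudovalue), mean_loo = mean(theta_loo),
    .groups = "drop")
  avg_theta <- dplyr::summarise(dplyr::group_by(th, factor1, reader),
                                fom = mean(fom), .groups = "drop")
  # ... and compare with pseudovalues built from the averaged FOMs
  chk <- dplyr::left_join(avg, avg_theta, by = c("factor1", "reader"))
  expect_equal(chk$mean_pseudo, K * chk$fom - (K - 1) * chk$mean_loo)
})

test_that("Welch reader-group comparison behaves at its limits", {
  d <- fom_tbl(rep(c(0.8, 0.9, 0.7, 0.85), each = 4), J = 4)
  groups <- c(R1 = "radiologist", R2 = "radiographer",
              R3 = "radiologist", R4 = "radiographer")
  same <- reader_group_ttest(
    rbind(d, transform(d, reader = paste0(reader, "b"))),
    c(groups, setNames(rev(unname(groups)), paste0(names(groups), "b"))))
  # both groups see the same FOM multiset -> no difference
  expect_equal(same$estimate, 0)
  expect_equal(same$p.value, 1)

  # per-reader values (readers vary slowest in fom_tbl): R1-R3 high, R4-R6 low
  sep <- fom_tbl(rep(c(0.901, 0.899, 0.9, 0.501, 0.499, 0.5), each = 4),
                 I1 = 2, I2 = 2, J = 6)
  g2 <- setNames(rep(c("A", "B"), each = 3), paste0("R", 1:6))
  res <- reader_group_ttest(sep, g2)
  expect_lt(res$p.value, 0.001)
  expect_equal(res$estimate, 0.4, tolerance = 0.01)
  expect_error(reader_group_ttest(d, c(R1 = "A", R2 = "A", R3 = "A",
                                       R4 = "B")), "at least 2")
})

test_that("Welch p agrees with a permutation test within Monte-Carlo error", {
  set.seed(77)
  foms <- c(0.82, 0.88, 0.79, 0.91, 0.70, 0.74, 0.69, 0.81)
  d <- data.frame(factor1 = "1", factor2 = "1",
                  reader = paste0("R", 1:8), fom = foms)
  g <- setNames(rep(c("A", "B"), each = 4), paste0("R", 1:8))
  welch <- reader_group_ttest(d, g)
  obs <- abs(mean(foms[1:4]) - mean(foms[5:8]))
  perm <- replicate(4000, {
    p <- sample(8)
    abs(mean(foms[p[1:4]]) - mean(foms[p[5:8]]))
  })
  p_perm <- mean(perm >= obs - 1e-12)
  expect_lt(abs(welch$p.value - p_perm), 0.05)
})
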