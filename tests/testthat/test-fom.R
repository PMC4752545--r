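test_that("psi kernel scores win/tie/loss, including the unmarked tie", {
  expect_equal(psi(5, 3), 1)
  expect_equal(psi(2, 7), 0)
  expect_equal(psi(-Inf, -Inf), 0.5)
  expect_equal(psi(-Inf, -Inf, tie = 0), 0)
  expect_equal(psi(c(1, 2, 3), c(2, 2, 2)), c(0, 0.5, 1))
})

test_that("hand-enumerated cell FOMs are reproduced", {
  # normals: highest NL 3 and unmarked; abnormals: one-lesion LL 5, unmarked
  expect_equal(wafroc_fom(ll = c(5, -Inf), fp = c(3, -Inf),
                          weights = c(1, 1)), 0.625)
  expect_equal(inferred_roc_fom(c(5, -Inf), c(3, -Inf)), 0.625)
  # perfect observer
  expect_equal(wafroc_fom(ll = c(9, 8), fp = c(3, -Inf), weights = c(1, 1)),
               1)
  # observer marking nothing scores 0.5 under the tie convention
  expect_equal(wafroc_fom(ll = c(-Inf, -Inf), fp = c(-Inf, -Inf),
                          weights = c(1, 1)), 0.5)
  expect_equal(inferred_roc_fom(c(4, 7), c(4, 7)), 0.5)  # symmetry
  expect_error(wafroc_fom(numeric(0), 3, numeric(0)), "undefined FOM")
})

test_that("both FOMs agree exactly with brute-force oracles", {
  for (s in 1:200) {
    ds <- random_small_froc(s)
    fm_w <- fom_matrix(ds, "wafroc")
    fm_r <- fom_matrix(ds, "roc")
    expect_equal(fm_w$fom, oracle_wafroc(ds$marks, ds$truth))
    expect_equal(fm_r$fom, oracle_roc(ds$marks, ds$truth))
  }
})

test_that("FOMs are invariant under strictly increasing rating transforms", {
  for (s in c(3, 17, 42)) {
    ds <- random_small_froc(s)
    tds <- ds
    tds$marks$rating <- exp(0.3 * tds$marks$rating) - 2
    expect_equal(fom_matrix(ds, "wafroc")$fom, fom_matrix(tds, "wafroc")$fom)
    expect_equal(fom_matrix(ds, "roc")$fom, fom_matrix(tds, "roc")$fom)
  }
})

test_that("NL marks on normal cases never help; higher LL never hurts", {
  for (s in 1:25) {
    ds <- random_small_froc(s)
    base_w <- fom_matrix(ds, "wafroc")$fom
    base_r <- fom_matrix(ds, "roc")$fom
    normals <- ds$truth$cases$case[!ds$truth$cases$abnormal]
    worse <- ds
    worse$marks <- rbind(ds$marks, data.frame(
      factor1 = "1", factor2 = "1", reader = "R1", case = normals[1],
      type = "NL", lesion = NA_character_, rating = 6))
    expect_lte(fom_matrix(worse, "wafroc")$fom, base_w)
    expect_lte(fom_matrix(worse, "roc")$fom, base_r)
    lls <- which(ds$marks$type == "LL")
    if (length(lls) > 0) {
      better <- ds
      better$marks$rating[lls[1]] <- better$marks$rating[lls[1]] + 5
      expect_gte(fom_matrix(better, "wafroc")$fom, base_w)
    }
  }
})

test_that("fom_matrix has one cell per design point and is local", {
  ds <- simulate_froc(sim_config(I1 = 4, I2 = 2, J = 11, K1 = 4, K2 = 4,
                                 seed = 2))
  fm <- fom_matrix(ds)
  expect_equal(nrow(fm), 4 * 2 * 11)
  expect_equal(dplyr::n_distinct(fm$factor1), 4)
  expect_equal(dplyr::n_distinct(fm$factor2), 2)
  expect_equal(dplyr::n_distinct(fm$reader), 11)
  # perturb one cell: only that cell's FOM changes
  ds2 <- ds
  hit <- ds2$marks$factor1 == "2" & ds2$marks$factor2 == "1" &
    ds2$marks$reader == "R03" & ds2$marks$type == "LL"
  skip_if(sum(hit) == 0)
  ds2$marks$rating[hit] <- ds2$marks$rating[hit] + 3
  fm2 <- fom_matrix(ds2)
  changed <- fm$fom != fm2$fom
  expect_true(all(paste(fm$factor1, fm$factor2, fm$reader)[changed] ==
                    "2 1 R03"))
})

test_that("jackknife matches deleted-case recomputation and its identities", {
  # hand example: delete the unmarked normal from the 4-case dataset
  truth <- froc_truth(
    cases = data.frame(case = c("N1", "N2", "A1", "A2"),
                       abnormal = c(FALSE, FALSE, TRUE, TRUE)),
    lesions = data.frame(case = c("A1", "A2"), lesion = "L1"))
  marks <- data.frame(factor1 = "1", factor2 = "1", reader = "R1",
                      case = c("N1", "A1"), type = c("NL", "LL"),
                      lesion = c(NA, "L1"), rating = c(3, 5))
  ds <- froc_data(marks, truth, check_complete = FALSE)
  jk <- jackknife_foms(ds)
  expect_equal(jk$theta_loo[jk$case == "N2"], 0.5)
  expect_equal(jk$pseudovalue[jk$case == "N2"], 4 * 0.625 - 3 * 0.5)

  # brute force agreement on a richer dataset
  cfg <- sim_config(I1 = 2, I2 = 1, J = 2, K1 = 4, K2 = 4, seed = 11)
  ds <- simulate_froc(cfg)
  for (fom in c("wafroc", "roc")) {
    jk <- jackknife_foms(ds, fom)
    for (cs in ds$truth$cases$case) {
      t2 <- froc_truth(ds$truth$cases[ds$truth$cases$case != cs, ],
                       ds$truth$lesions[ds$truth$lesions$case != cs, ])
      ds2 <- froc_data(ds$marks[ds$marks$case != cs, ], t2,
                       rating_range = ds$rating_range,
                       factor1_levels = ds$factor1_levels,
                       factor2_levels = ds$factor2_levels,
                       readers = ds$readers, check_complete = FALSE)
      cmp <- dplyr::left_join(jk[jk$case == cs, ], fom_matrix(ds2, fom),
                              by = c("factor1", "factor2", "reader"))
      expect_equal(cmp$theta_loo, cmp$fom)
    }
    # algebraic identity: mean(Y_k) = K theta - (K - 1) mean(theta_(k))
    K <- attr(jk, "K")
    agg <- dplyr::summarise(
      dplyr::group_by(jk, factor1, factor2, reader),
      mY = mean(pseudovalue), mloo = mean(theta_loo), .groups = "drop")
    agg <- dplyr::left_join(agg, attr(jk, "theta"),
                            by = c("factor1", "factor2", "reader"))
    expect_equal(agg$mY, K * agg$fom - (K - 1) * agg$mloo)
  }
})

test_that("when every case contributes identically all pseudovalues equal theta", {
  truth <- froc_truth(
    cases = data.frame(case = c("N1", "N2", "A1", "A2"),
                       abnormal = c(FALSE, FALSE, TRUE, TRUE)),
    lesions = data.frame(case = c("A1", "A2"), lesion = "L1"))
  empty <- data.frame(factor1 = character(), factor2 = character(),
                      reader = character(), case = character(),
                      type = character(), lesion = character(),
                      rating = numeric())
  ds <- froc_data(empty, truth, check_complete = FALSE)
  ds$factor1_levels <- "1"; ds$factor2_levels <- "1"; ds$readers <- "R1"
  jk <- jackknife_foms(ds)
  expect_true(all(jk$theta_loo == 0.5))
  expect_true(all(jk$pseudovalue == 0.5))
})
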