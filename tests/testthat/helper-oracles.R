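# Independent brute-force oracles and small random fixtures.
#
# The oracles enumerate every (normal case, abnormal case, lesion) pair with
# explicit loops straight from the marks table, sharing no code path with
# the package's vectorised FOM implementation.

psi_scalar <- function(a, b, tie = 0.5) {
  if (a > b) 1 else if (a < b) 0 else tie
}

# highest NL rating on a case (-Inf if none)
oracle_fp <- function(marks, case_id) {
  r <- marks$rating[marks$case == case_id & marks$type == "NL"]
  if (length(r) == 0) -Inf else max(r)
}

oracle_highest <- function(marks, case_id) {
  r <- marks$rating[marks$case == case_id]
  if (length(r) == 0) -Inf else max(r)
}

oracle_ll <- function(marks, case_id, lesion_id) {
  r <- marks$rating[marks$case == case_id & marks$type == "LL" &
                      !is.na(marks$lesion) & marks$lesion == lesion_id]
  if (length(r) == 0) -Inf else max(r)
}

# wAFROC for one design cell, by triple loop
oracle_wafroc <- function(marks, truth, tie = 0.5) {
  normals <- truth$cases$case[!truth$cases$abnormal]
  abnormals <- truth$cases$case[truth$cases$abnormal]
  total <- 0
  for (n_case in normals) {
    fp <- oracle_fp(marks, n_case)
    for (a_case in abnormals) {
      les <- truth$lesions[truth$lesions$case == a_case, ]
      for (l in seq_len(nrow(les))) {
        ll <- oracle_ll(marks, a_case, les$lesion[l])
        total <- total + les$weight[l] * psi_scalar(ll, fp, tie)
      }
    }
  }
  total / (length(normals) * length(abnormals))
}

# inferred-ROC area for one design cell, by double loop
oracle_roc <- function(marks, truth, tie = 0.5) {
  normals <- truth$cases$case[!truth$cases$abnormal]
  abnormals <- truth$cases$case[truth$cases$abnormal]
  total <- 0
  for (n_case in normals) {
    hn <- oracle_highest(marks, n_case)
    for (a_case in abnormals) {
      total <- total + psi_scalar(oracle_highest(marks, a_case), hn, tie)
    }
  }
  total / (length(normals) * length(abnormals))
}

# random one-cell dataset with K1, K2 <= 5 and 1-3 lesions per abnormal case
random_small_froc <- function(seed, integer_ratings = TRUE) {
  set.seed(seed)
  k1 <- sample(1:5, 1); k2 <- sample(1:5, 1)
  normals <- sprintf("N%d", seq_len(k1))
  abnormals <- sprintf("A%d", seq_len(k2))
  nles <- sample(1:3, k2, replace = TRUE)
  truth <- froc_truth(
    cases = data.frame(case = c(normals, abnormals),
                       abnormal = rep(c(FALSE, TRUE), c(k1, k2))),
    lesions = data.frame(case = rep(abnormals, nles),
                         lesion = unlist(lapply(nles, function(n)
                           sprintf("L%d", 1:n)))))
  rate <- function(n) if (integer_ratings) sample(1:10, n, TRUE) else
    round(rnorm(n, 3, 2), 3)
  rows <- list()
  for (cs in c(normals, abnormals)) {
    n_nl <- sample(0:2, 1)
    if (n_nl > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        factor1 = "1", factor2 = "1", reader = "R1", case = cs, type = "NL",
        lesion = NA_character_, rating = rate(n_nl))
    }
  }
  for (i in seq_len(k2)) {
    hit <- runif(nles[i]) < 0.7
    if (any(hit)) {
      rows[[length(rows) + 1]] <- data.frame(
        factor1 = "1", factor2 = "1", reader = "R1", case = abnormals[i],
        type = "LL", lesion = sprintf("L%d", which(hit)),
        rating = rate(sum(hit)))
    }
  }
  if (length(rows) > 0) {
    marks <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    marks <- data.frame(factor1 = character(), factor2 = character(),
                        reader = character(), case = character(),
                        type = character(), lesion = character(),
                        rating = numeric())
  }
  froc_data(marks, truth, rating_range = c(-Inf, Inf),
            factor1_levels = "1", factor2_levels = "1", readers = "R1",
            check_complete = FALSE)
}

# I x J matrix of plausible FOM values
random_fom_matrix <- function(seed, I = 2, J = 5) {
  set.seed(seed)
  matrix(runif(I * J, 0.5, 1), nrow = I,
         dimnames = list(paste0("T", 1:I), paste0("R", 1:J)))
}
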