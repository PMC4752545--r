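#' Construct a lesion truth table
#'
#' A truth table defines the case set of a free-response study: which cases
#' are normal, which are abnormal, and for abnormal cases the location and
#' identity of every true lesion. Lesion weights default to equal weighting
#' within a case (`1 / n_lesions`), which gives every case the same importance
#' in the wAFROC figure of merit regardless of its lesion count.
#'
#' @param cases Data frame with columns `case` (identifier) and `abnormal`
#'   (logical). Every case in the study appears exactly once.
#' @param lesions Data frame with columns `case` and `lesion` (identifiers),
#'   and optionally `x`, `y` (pixel coordinates), `diameter_mm`, `density_hu`,
#'   `side`, `level`, `depth`, `peripheral` (zone labels) and `weight`. May be
#'   `NULL` when all cases are normal.
#' @param check Abort on invariant violations (default). With `check = FALSE`
#'   the object is built as-is so that [validate_froc()] can report on it.
#'
#' @return A `froc_truth` object: a list with tibbles `cases` and `lesions`.
#' @seealso [read_truth_csv()], [make_phantom_truth()]
#' @export
froc_truth <- function(cases, lesions = NULL, check = TRUE) {
  cases <- as_tibble(cases)
  stopifnot(all(c("case", "abnormal") %in% names(cases)))
  cases <- mutate(cases, case = as.character(.data$case),
                  abnormal = as.logical(.data$abnormal))
  if (is.null(lesions)) {
    lesions <- tibble(case = character(), lesion = character(),
                      weight = numeric())
  }
  lesions <- as_tibble(lesions)
  stopifnot(all(c("case", "lesion") %in% names(lesions)))
  lesions <- mutate(lesions, case = as.character(.data$case),
                    lesion = as.character(.data$lesion))
  if (!"weight" %in% names(lesions) ||
      all(is.na(lesions$weight))) {
    lesions <- lesions %>%
      group_by(.data$case) %>%
      mutate(weight = 1 / n()) %>%
      ungroup()
  }
  out <- structure(list(cases = cases, lesions = arrange(lesions, .data$case,
                                                         .data$lesion)),
                   class = "froc_truth")
  if (check) {
    bad <- truth_violations(out)
    if (nrow(bad) > 0) {
      abort(paste0("invalid truth table:\n",
                   paste("-", bad$detail, collapse = "\n")))
    }
  }
  out
}

truth_violations <- function(truth) {
  v <- list()
  dup <- truth$cases$case[duplicated(truth$cases$case)]
  if (length(dup) > 0) {
    v <- c(v, paste("duplicated case id:", unique(dup)))
  }
  normal <- truth$cases$case[!truth$cases$abnormal]
  abnormal <- truth$cases$case[truth$cases$abnormal]
  on_normal <- unique(truth$lesions$case[truth$lesions$case %in% normal])
  if (length(on_normal) > 0) {
    v <- c(v, paste("lesion on normal case:", on_normal))
  }
  unknown <- setdiff(unique(truth$lesions$case), truth$cases$case)
  if (length(unknown) > 0) {
    v <- c(v, paste("lesion on unknown case:", unknown))
  }
  empty <- setdiff(abnormal, truth$lesions$case)
  if (length(empty) > 0) {
    v <- c(v, paste("abnormal case without lesions:", empty))
  }
  wsum <- truth$lesions %>%
    group_by(.data$case) %>%
    summarise(w = sum(.data$weight), .groups = "drop") %>%
    filter(abs(.data$w - 1) > 1e-8)
  if (nrow(wsum) > 0) {
    v <- c(v, paste0("lesion weights on case ", wsum$case,
                     " sum to ", signif(wsum$w, 6), ", not 1"))
  }
  tibble(check = "truth", detail = unlist(v) %||% character())
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.froc_truth <- function(x, ...) {
  k2 <- sum(x$cases$abnormal)
  cat("<froc_truth> ", nrow(x$cases), " cases (",
      nrow(x$cases) - k2, " normal, ", k2, " abnormal), ",
      nrow(x$lesions), " lesions\n", sep = "")
  invisible(x)
}

#' Construct a scored factorial FROC dataset
#'
#' A scored dataset holds every rated mark of a fully crossed two-factor
#' FROC study: each mark is either a lesion localization (`LL`, a mark
#' credited to a specific true lesion) or a non-lesion localization (`NL`).
#' Unmarked lesions and cases with no marks are not stored; they enter the
#' figure-of-merit computations through the unmarked sentinel (-Inf), which
#' lies strictly below any legal rating.
#'
#' The design must be complete: every combination of factor levels and
#' readers covers the full case set. Because a reader who makes no mark in a
#' design cell contributes no rows, completeness is checked as "every
#' (factor1, factor2, reader) combination of the declared level sets appears
#' at least once in `marks`" unless `check_complete = FALSE` (used by the
#' simulator, whose designs are complete by construction).
#'
#' @param marks Data frame with columns `factor1`, `factor2`, `reader`,
#'   `case`, `type` (`"NL"` or `"LL"`), `lesion` (`NA` for NL rows) and
#'   `rating`.
#' @param truth A [froc_truth()] object.
#' @param rating_range Numeric length-2 legal rating bounds. The study design
#'   this package ships with uses an integer 1-10 scale, but continuous
#'   ratings (e.g. from the simulator) are accepted.
#' @param factor1_levels,factor2_levels,readers Optional explicit level sets
#'   (in display order); default: sorted unique values observed in `marks`.
#' @param check_complete Check design completeness (see above).
#'
#' @return A `froc_data` object.
#' @seealso [read_scored_csv()], [classify_marks()], [simulate_froc()],
#'   [fom_matrix()]
#' @export
froc_data <- function(marks, truth, rating_range = c(1, 10),
                      factor1_levels = NULL, factor2_levels = NULL,
                      readers = NULL, check_complete = TRUE) {
  stopifnot(inherits(truth, "froc_truth"))
  marks <- as_tibble(marks)
  need <- c("factor1", "factor2", "reader", "case", "type", "lesion", "rating")
  missing_cols <- setdiff(need, names(marks))
  if (length(missing_cols) > 0) {
    abort(paste("marks is missing columns:",
                paste(missing_cols, collapse = ", ")))
  }
  marks <- marks %>%
    mutate(factor1 = as.character(.data$factor1),
           factor2 = as.character(.data$factor2),
           reader = as.character(.data$reader),
           case = as.character(.data$case),
           type = as.character(.data$type),
           lesion = as.character(.data$lesion),
           rating = as.numeric(.data$rating)) %>%
    select(dplyr::all_of(need))

  lvl <- function(given, observed) {
    if (!is.null(given)) as.character(given) else sort(unique(observed))
  }
  factor1_levels <- lvl(factor1_levels, marks$factor1)
  factor2_levels <- lvl(factor2_levels, marks$factor2)
  readers <- lvl(readers, marks$reader)

  if (!all(marks$type %in% c("NL", "LL"))) {
    abort("mark type must be 'NL' or 'LL'")
  }
  unknown <- setdiff(unique(marks$case), truth$cases$case)
  if (length(unknown) > 0) {
    abort(paste("truth mismatch: marks reference unknown case(s):",
                paste(unknown, collapse = ", ")))
  }
  ll <- filter(marks, .data$type == "LL")
  known_lesions <- paste(truth$lesions$case, truth$lesions$lesion)
  bad_ll <- !(paste(ll$case, ll$lesion) %in% known_lesions)
  if (any(bad_ll)) {
    abort(paste("truth mismatch: LL rows name nonexistent lesions on case(s):",
                paste(unique(ll$case[bad_ll]), collapse = ", ")))
  }
  out_of_range <- marks$rating < rating_range[1] | marks$rating > rating_range[2]
  if (any(out_of_range)) {
    abort(paste0("ratings outside [", rating_range[1], ", ", rating_range[2],
                 "] in ", sum(out_of_range), " row(s)"))
  }
  if (check_complete && nrow(marks) > 0) {
    seen <- distinct(marks, .data$factor1, .data$factor2, .data$reader)
    full <- tidyr::expand_grid(factor1 = factor1_levels,
                               factor2 = factor2_levels, reader = readers)
    missing_cells <- dplyr::anti_join(
      full, seen, by = c("factor1", "factor2", "reader"))
    if (nrow(missing_cells) > 0) {
      abort(paste0("incomplete design: no rows for ", nrow(missing_cells),
                   " (factor1, factor2, reader) cell(s), e.g. (",
                   missing_cells$factor1[1], ", ", missing_cells$factor2[1],
                   ", ", missing_cells$reader[1], ")"))
    }
  }
  structure(list(marks = marks, truth = truth, rating_range = rating_range,
                 factor1_levels = factor1_levels,
                 factor2_levels = factor2_levels, readers = readers),
            class = "froc_data")
}

#' @export
print.froc_data <- function(x, ...) {
  cat("<froc_data> ", length(x$factor1_levels), " x ",
      length(x$factor2_levels), " factor levels, ",
      length(x$readers), " readers, ",
      nrow(x$truth$cases), " cases; ",
      sum(x$marks$type == "LL"), " LL and ",
      sum(x$marks$type == "NL"), " NL marks\n", sep = "")
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.froc_data <- function(x, ...) x$marks

#' Design dimensions of a scored dataset
#'
#' @param ds A `froc_data` object.
#' @return Named list with `I1`, `I2`, `J`, `K1` (normal cases), `K2`
#'   (abnormal cases) and `n_lesions`.
#' @export
froc_dims <- function(ds) {
  stopifnot(inherits(ds, "froc_data"))
  list(I1 = length(ds$factor1_levels), I2 = length(ds$factor2_levels),
       J = length(ds$readers), K1 = sum(!ds$truth$cases$abnormal),
       K2 = sum(ds$truth$cases$abnormal), n_lesions = nrow(ds$truth$lesions))
}

#' Validate a scored FROC dataset
#'
#' Report-based checking: returns one row per invariant violation instead of
#' aborting, so that questionable files can be inspected. An empty report
#' means the dataset satisfies all invariants: ratings within the legal
#' bounds, per-case lesion weights summing to one, lesions attached to
#' abnormal cases only, LL rows naming true lesions, and at most one LL
#' rating per lesion within a design cell.
#'
#' @param ds A `froc_data` object.
#' @return A tibble with columns `check` and `detail`; zero rows iff valid.
#' @export
validate_froc <- function(ds) {
  stopifnot(inherits(ds, "froc_data"))
  out <- truth_violations(ds$truth)
  m <- ds$marks
  oob <- m$rating < ds$rating_range[1] | m$rating > ds$rating_range[2]
  if (any(oob)) {
    out <- bind_rows(out, tibble(
      check = "rating_bounds",
      detail = paste0(sum(oob), " rating(s) outside [",
                      ds$rating_range[1], ", ", ds$rating_range[2], "]")))
  }
  ll <- filter(m, .data$type == "LL")
  known <- paste(ds$truth$lesions$case, ds$truth$lesions$lesion)
  bad <- !(paste(ll$case, ll$lesion) %in% known)
  if (any(bad)) {
    out <- bind_rows(out, tibble(
      check = "lesion_reference",
      detail = paste0(sum(bad), " LL row(s) name nonexistent lesions")))
  }
  dup <- ll %>%
    count(.data$factor1, .data$factor2, .data$reader, .data$case,
          .data$lesion) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    out <- bind_rows(out, tibble(
      check = "duplicate_ll",
      detail = paste0(nrow(dup), " lesion(s) rated more than once in a cell")))
  }
  out
}

#' Read / write scored FROC ratings as CSV
#'
#' The scored CSV format has columns
#' `factor1,factor2,reader,case,type,lesion,rating`, one row per mark;
#' `type` is `NL` or `LL` and `lesion` is empty for NL rows. Only marked
#' entities produce rows; unmarked lesions are implicit.
#'
#' @param path File path.
#' @param truth A [froc_truth()] object describing the case set.
#' @inheritParams froc_data
#' @return For `read_scored_csv`, a validated `froc_data`; for
#'   `write_scored_csv`, `path`, invisibly.
#' @export
read_scored_csv <- function(path, truth, rating_range = c(1, 10),
                            check_complete = TRUE) {
  marks <- readr::read_csv(path, col_types = readr::cols(
    factor1 = readr::col_character(), factor2 = readr::col_character(),
    reader = readr::col_character(), case = readr::col_character(),
    type = readr::col_character(), lesion = readr::col_character(),
    rating = readr::col_double()))
  froc_data(marks, truth, rating_range = rating_range,
            check_complete = check_complete)
}

#' @param ds A `froc_data` object.
#' @rdname read_scored_csv
#' @export
write_scored_csv <- function(ds, path) {
  stopifnot(inherits(ds, "froc_data"))
  readr::write_csv(ds$marks, path, na = "")
  invisible(path)
}

#' Read / write a truth table as CSV
#'
#' Columns:
#' `case,abnormal,lesion,x,y,diameter_mm,density_hu,side,level,depth,peripheral,weight`.
#' Normal cases appear as a single row with empty lesion fields.
#'
#' @param path File path.
#' @return For `read_truth_csv`, a `froc_truth`; for `write_truth_csv`,
#'   `path`, invisibly.
#' @export
read_truth_csv <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    case = readr::col_character(), abnormal = readr::col_logical(),
    lesion = readr::col_character(), x = readr::col_double(),
    y = readr::col_double(), diameter_mm = readr::col_double(),
    density_hu = readr::col_double(), side = readr::col_character(),
    level = readr::col_character(), depth = readr::col_character(),
    peripheral = readr::col_logical(), weight = readr::col_double()))
  cases <- distinct(raw, .data$case, .data$abnormal)
  lesions <- raw %>%
    filter(!is.na(.data$lesion)) %>%
    select(-"abnormal")
  froc_truth(cases, lesions)
}

#' @param truth A `froc_truth` object.
#' @rdname read_truth_csv
#' @export
write_truth_csv <- function(truth, path) {
  stopifnot(inherits(truth, "froc_truth"))
  les_cols <- c("lesion", "x", "y", "diameter_mm", "density_hu", "side",
                "level", "depth", "peripheral", "weight")
  les <- truth$lesions
  for (cc in setdiff(les_cols, names(les))) les[[cc]] <- NA
  out <- left_join(truth$cases, les[, c("case", les_cols)], by = "case") %>%
    arrange(.data$case, .data$lesion)
  readr::write_csv(out, path, na = "")
  invisible(path)
}
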