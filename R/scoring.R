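#' Classify raw observer marks against a truth table
#'
#' Turns raw mark-and-rate records (`x`, `y`, `rating`) into a scored FROC
#' dataset by comparing each mark with the true lesion locations of its case.
#' A mark is a lesion localization (LL) when its Euclidean distance to the
#' nearest lesion is at most `radius` pixels (the boundary counts as within);
#' otherwise it is a non-lesion localization (NL). All marks on normal cases
#' are NLs. When several marks land on the same lesion within one design
#' cell, the lesion's LL rating is the highest of them; the surplus marks are
#' either discarded (default; a deliberate mark-and-rate interface yields one
#' perception event per perceived lesion) or demoted to NL marks for
#' sensitivity analysis.
#'
#' Distance ties between two equally near lesions are broken toward the
#' lexicographically smallest lesion id, so scoring is deterministic and
#' invariant under relabelling (relabelling permutes ids but each mark stays
#' with the same physical lesion unless it is exactly equidistant).
#'
#' @param marks Data frame of raw marks with columns `factor1`, `factor2`,
#'   `reader`, `case`, `x`, `y`, `rating`.
#' @param truth A [froc_truth()] with lesion `x`, `y` coordinates in pixels.
#' @param radius Acceptance radius in pixels; must be positive. Default 20.
#' @param surplus Policy for lower-rated repeat marks on an already credited
#'   lesion: `"discard"` (default) or `"demote"` (re-classified as NL).
#' @inheritParams froc_data
#' @return A `froc_data` object.
#' @examples
#' truth <- froc_truth(
#'   cases = data.frame(case = c("A1", "N1"), abnormal = c(TRUE, FALSE)),
#'   lesions = data.frame(case = "A1", lesion = "L1", x = 100, y = 100))
#' marks <- data.frame(factor1 = "10", factor2 = "FBP", reader = "R1",
#'                     case = c("A1", "N1"), x = c(110, 300), y = c(100, 40),
#'                     rating = c(8, 2))
#' classify_marks(marks, truth)$marks
#' @export
classify_marks <- function(marks, truth, radius = 20,
                           surplus = c("discard", "demote"),
                           rating_range = c(1, 10), check_complete = TRUE) {
  surplus <- match.arg(surplus)
  stopifnot(inherits(truth, "froc_truth"), is.numeric(radius), radius > 0)
  marks <- as_tibble(marks)
  need <- c("factor1", "factor2", "reader", "case", "x", "y", "rating")
  stopifnot(all(need %in% names(marks)))
  marks <- marks %>%
    mutate(dplyr::across(dplyr::all_of(c("factor1", "factor2", "reader",
                                         "case")), as.character),
           .mark = dplyr::row_number())
  unknown <- setdiff(unique(marks$case), truth$cases$case)
  if (length(unknown) > 0) {
    abort(paste("truth mismatch: marks on unknown case(s):",
                paste(unknown, collapse = ", ")))
  }
  les <- truth$lesions %>%
    select("case", "lesion", lx = "x", ly = "y")

  # nearest lesion per mark (many-to-many join is the candidate enumeration)
  cand <- marks %>%
    dplyr::inner_join(les, by = "case", relationship = "many-to-many") %>%
    mutate(dist = sqrt((.data$x - .data$lx)^2 + (.data$y - .data$ly)^2)) %>%
    filter(.data$dist <= radius) %>%
    arrange(.data$.mark, .data$dist, .data$lesion) %>%
    distinct(.data$.mark, .keep_all = TRUE) %>%
    select(".mark", "lesion")

  scored <- left_join(marks, cand, by = ".mark") %>%
    mutate(type = ifelse(is.na(.data$lesion), "NL", "LL"))

  # one LL per lesion per cell: keep the highest rating, handle the rest
  ll <- scored %>%
    filter(.data$type == "LL") %>%
    group_by(.data$factor1, .data$factor2, .data$reader, .data$case,
             .data$lesion) %>%
    arrange(dplyr::desc(.data$rating), .data$.mark, .by_group = TRUE) %>%
    mutate(.rank = dplyr::row_number()) %>%
    ungroup()
  kept_ll <- filter(ll, .data$.rank == 1)
  extra <- filter(ll, .data$.rank > 1)
  if (surplus == "demote" && nrow(extra) > 0) {
    extra <- mutate(extra, type = "NL", lesion = NA_character_)
  } else {
    extra <- extra[0, ]
  }
  out <- bind_rows(filter(scored, .data$type == "NL"),
                   select(kept_ll, -".rank"),
                   select(extra, -".rank")) %>%
    arrange(.data$.mark) %>%
    select("factor1", "factor2", "reader", "case", "type", "lesion", "rating")
  froc_data(out, truth, rating_range = rating_range,
            check_complete = check_complete)
}
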