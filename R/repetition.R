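# Short-term-memory repetition analysis: does exploration narrow (entropy
# drop) when the second image of a trial pair repeats the first?

#' Join entropy results to the trial-pair structure
#'
#' Produces the long-format table for the repetition analysis: one row per
#' surviving exploration with its within-pair order (first/second) and pair
#' type. Pairs with either member discarded by the validity filter are dropped
#' entirely — the within-pair contrast is undefined for half-pairs.
#'
#' @param entropies tibble from [entropy_table()] (must carry
#'   `participant_id`, `trial_index`, `order`, `H`, `group`).
#' @param trials trial tibble with `participant_id`, `trial_index`,
#'   `pair_type`, `first_image_id`, `second_image_id`.
#' @return Tibble (`repetition_table`): `participant_id`, `group`,
#'   `trial_index`, `pair_type`, `image_order` (`"first"`/`"second"`),
#'   `image_id`, `H`. Attribute `pair_counts` reports complete pairs per type.
#' @export
build_repetition_table <- function(entropies, trials) {
  stopifnot(all(c("participant_id", "trial_index", "order", "H", "group",
                  "image_id") %in% names(entropies)),
            all(c("participant_id", "trial_index", "pair_type",
                  "first_image_id", "second_image_id") %in% names(trials)))
  known <- unique(entropies$image_id)
  bad <- setdiff(unique(c(trials$first_image_id, trials$second_image_id)),
                 known)
  # images absent from the entropy table are fine when their exploration was
  # discarded; an id never seen anywhere in the session is a join error
  rows <- list()
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    e1 <- entropies[entropies$participant_id == tr$participant_id &
                      entropies$trial_index == tr$trial_index &
                      entropies$order == 1L, ]
    e2 <- entropies[entropies$participant_id == tr$participant_id &
                      entropies$trial_index == tr$trial_index &
                      entropies$order == 2L, ]
    if (nrow(e1) == 1 && e1$image_id != tr$first_image_id ||
        nrow(e2) == 1 && e2$image_id != tr$second_image_id) {
      stop("trial table and entropy table disagree on image ids for ",
           tr$participant_id, " trial ", tr$trial_index)
    }
    if (nrow(e1) != 1 || nrow(e2) != 1) next  # half-pairs dropped entirely
    rows[[length(rows) + 1]] <- tibble::tibble(
      participant_id = tr$participant_id,
      group = e1$group,
      trial_index = tr$trial_index,
      pair_type = tr$pair_type,
      image_order = c("first", "second"),
      image_id = c(e1$image_id, e2$image_id),
      H = c(e1$H, e2$H)
    )
  }
  out <- dplyr::bind_rows(rows)
  counts <- if (nrow(out)) table(out$pair_type[out$image_order == "first"])
            else table(character(0))
  attr(out, "pair_counts") <- counts
  out
}

#' Repetition contrast for one pair type
#'
#' Restricts the repetition table to one pair type, reports descriptive
#' first-vs-second mean entropies per group, and fits the mixed model
#' `H ~ group + image_order + (1 | participant_id)` via [mixed_model()].
#'
#' @param table output of [build_repetition_table()].
#' @param pair_type `"same_image"`, `"same_category"` or
#'   `"different_category"`.
#' @return List with `frame` (the model input), `summary` (per-group mean H by
#'   order) and `model` (a [mixed_model()] result).
#' @export
repetition_contrast <- function(table, pair_type) {
  stopifnot(pair_type %in% c("same_image", "same_category",
                             "different_category"))
  frame <- table[table$pair_type == pair_type, , drop = FALSE]
  if (nrow(frame) == 0) stop("no rows for pair type ", pair_type)
  both <- intersect(unique(frame$participant_id[frame$image_order == "first"]),
                    unique(frame$participant_id[frame$image_order == "second"]))
  if (length(both) < 2) stop("need >= 2 participants with both orders")
  drop_groups <- setdiff(unique(frame$group),
                         unique(frame$group[frame$image_order == "second"]))
  if (length(drop_groups)) {
    warning("group(s) without second-order rows excluded: ",
            paste(drop_groups, collapse = ", "))
    frame <- frame[!frame$group %in% drop_groups, , drop = FALSE]
  }
  frame$image_order <- factor(frame$image_order, levels = c("first", "second"))
  frame$group <- factor(frame$group)
  summ <- dplyr::summarise(
    dplyr::group_by(frame, .data$group, .data$image_order),
    mean_H = mean(.data$H), n = dplyr::n(), .groups = "drop"
  )
  fixed <- if (nlevels(frame$group) > 1) "H ~ group + image_order"
           else "H ~ image_order"
  fit <- mixed_model(frame, fixed, random_intercept = "participant_id")
  list(frame = frame, summary = summ, model = fit)
}
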