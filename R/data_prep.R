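#' Breed group from Holstein-Friesian blood fraction
#'
#' Thai dairy cattle are Holstein-Friesian upgrades; records are classed by
#' HF blood level: group 1 below 87.5\%, group 2 from 87.5\% to 93.75\%
#' (boundaries included), group 3 above 93.75\%.
#'
#' @param hf_fraction Numeric vector in \[0, 1\].
#' @return Integer vector of breed groups 1-3.
#' @export
assign_breed_group <- function(hf_fraction) {
  if (any(hf_fraction < 0 | hf_fraction > 1, na.rm = TRUE)) {
    abort("`hf_fraction` must lie in [0, 1].")
  }
  dplyr::case_when(
    hf_fraction < 0.875 ~ 1L,
    hf_fraction <= 0.9375 ~ 2L,
    TRUE ~ 3L
  )
}

#' Calving season from calving month
#'
#' Thai seasons: winter November-February, summer March-June, rainy
#' July-October.
#'
#' @param calving_month Integer month 1-12.
#' @return Factor with levels `winter`, `summer`, `rainy`.
#' @export
assign_season <- function(calving_month) {
  if (any(!calving_month %in% 1:12)) abort("`calving_month` must be 1..12.")
  factor(
    dplyr::case_when(
      calving_month >= 11 | calving_month <= 2 ~ "winter",
      calving_month <= 6 ~ "summer",
      TRUE ~ "rainy"
    ),
    levels = c("winter", "summer", "rainy")
  )
}

#' Stage-of-lactation month
#'
#' Monthly stage class `ceiling(dim / 30.5)` capped at 11, so eleven classes
#' span DIM 1-305 (the TD1..TD11 monthly tests).
#'
#' @param dim Days in milk.
#' @return Integer stage 1-11.
#' @export
stage_month <- function(dim) {
  pmin(as.integer(ceiling(dim / 30.5)), 11L)
}

#' Record edit thresholds
#'
#' The data edits applied before analysis: age at calving restricted to
#' 18-48, 30-60 and 41-75 months for lactations 1-3; first test between 5
#' and 35 days from parturition; daily milk yields between 2 and 40 kg
#' (violating tests dropped); at least 5 tests per lactation; last test at
#' 150 days in milk or later; tests beyond DIM 305 dropped; later lactations
#' require all earlier ones; sires identified. `strict_traits = TRUE`
#' additionally drops any test missing fat or protein (the default keeps
#' such tests with the missing traits absent).
#'
#' @param milk_range,dim_range,first_td_window Length-2 numeric bounds.
#' @param min_td Minimum tests per cow-lactation.
#' @param min_last_dim Minimum DIM of the last retained test.
#' @param age_windows List of length-2 age bounds named "1", "2", "3".
#' @param require_sequence,require_sire,strict_traits Logical switches.
#' @return A list of class `edit_rules`.
#' @export
edit_rules <- function(milk_range = c(2, 40),
                       dim_range = c(1, 305),
                       first_td_window = c(5, 35),
                       min_td = 5L,
                       min_last_dim = 150,
                       age_windows = list(`1` = c(18, 48),
                                          `2` = c(30, 60),
                                          `3` = c(41, 75)),
                       require_sequence = TRUE,
                       require_sire = TRUE,
                       strict_traits = FALSE) {
  structure(
    list(milk_range = milk_range, dim_range = dim_range,
         first_td_window = first_td_window, min_td = as.integer(min_td),
         min_last_dim = min_last_dim, age_windows = age_windows,
         require_sequence = require_sequence, require_sire = require_sire,
         strict_traits = strict_traits),
    class = "edit_rules"
  )
}

edit_rule_names <- c("milk_range", "dim_range", "strict_traits",
                     "first_td_window", "min_td_count", "min_last_dim",
                     "age_window", "sequence", "sire_known")

#' Apply the record edits
#'
#' Drops out-of-range tests and removes cow-lactations violating the edit
#' rules, in a fixed order that makes the removal report deterministic:
#' test-level drops first (milk outside bounds, DIM outside bounds, and in
#' strict mode tests missing fat/protein), then cow-lactation checks
#' (first-test window, minimum test count, last-test DIM, age window,
#' lactation-sequence completeness, sire known). A cow-lactation is
#' attributed to the first rule it fails; one whose raw test count met the
#' minimum but fell below it through test drops is attributed to the
#' dropping rule. Removing a lactation invalidates the same cow's later
#' lactations through the sequence rule. Edits are idempotent.
#'
#' @param records Test-day tibble (see [read_testday()]).
#' @param rules An [edit_rules()] list.
#' @return The retained records, with the removal report attached as
#'   attribute `"removal_report"` (see [edit_report()]): one row per rule
#'   with the number of tests dropped and cow-lactations removed.
#' @export
apply_edits <- function(records, rules = edit_rules()) {
  rec <- tibble::as_tibble(records)
  if (!"sire_known" %in% names(rec)) rec$sire_known <- TRUE

  td_dropped <- setNames(integer(length(edit_rule_names)), edit_rule_names)
  cl_removed <- td_dropped

  # --- test-level drops, in order
  raw_counts <- dplyr::count(rec, .data$cow, .data$lactation,
                             name = "n_raw")
  drop_rule <- rep(NA_character_, nrow(rec))
  bad <- rec$milk < rules$milk_range[1] | rec$milk > rules$milk_range[2]
  drop_rule[bad & is.na(drop_rule)] <- "milk_range"
  bad <- rec$dim < rules$dim_range[1] | rec$dim > rules$dim_range[2]
  drop_rule[bad & is.na(drop_rule)] <- "dim_range"
  if (isTRUE(rules$strict_traits)) {
    bad <- is.na(rec$fat) | is.na(rec$protein)
    drop_rule[bad & is.na(drop_rule)] <- "strict_traits"
  }
  td_dropped[names(td_dropped)] <-
    vapply(names(td_dropped),
           function(r) sum(drop_rule == r, na.rm = TRUE), integer(1))
  first_drop <- rec |>
    dplyr::mutate(.drop = drop_rule) |>
    dplyr::filter(!is.na(.data$.drop)) |>
    dplyr::distinct(.data$cow, .data$lactation, .keep_all = TRUE) |>
    dplyr::select("cow", "lactation", first_drop_rule = ".drop")
  rec <- rec[is.na(drop_rule), ]

  # --- cow-lactation checks
  cl <- rec |>
    dplyr::group_by(.data$cow, .data$lactation) |>
    dplyr::summarise(
      n_td = dplyr::n(),
      first_dim = min(.data$dim),
      last_dim = max(.data$dim),
      age = .data$age_calving[1],
      sire_known = .data$sire_known[1],
      .groups = "drop"
    ) |>
    dplyr::left_join(raw_counts, by = c("cow", "lactation")) |>
    dplyr::left_join(first_drop, by = c("cow", "lactation"))

  age_lo <- vapply(as.character(cl$lactation),
                   function(l) rules$age_windows[[l]][1], numeric(1))
  age_hi <- vapply(as.character(cl$lactation),
                   function(l) rules$age_windows[[l]][2], numeric(1))

  fail <- rep(NA_character_, nrow(cl))
  mark <- function(fail, cond, rule) {
    ifelse(is.na(fail) & cond, rule, fail)
  }
  fail <- mark(fail, cl$first_dim < rules$first_td_window[1] |
                     cl$first_dim > rules$first_td_window[2],
               "first_td_window")
  short <- cl$n_td < rules$min_td
  # attribute the shortfall to the dropping rule when drops caused it
  idx <- is.na(fail) & short & cl$n_raw >= rules$min_td &
    !is.na(cl$first_drop_rule)
  fail[idx] <- cl$first_drop_rule[idx]
  fail <- mark(fail, short, "min_td_count")
  fail <- mark(fail, cl$last_dim < rules$min_last_dim, "min_last_dim")
  fail <- mark(fail, cl$age < age_lo | cl$age > age_hi, "age_window")
  if (isTRUE(rules$require_sire)) {
    fail <- mark(fail, !cl$sire_known, "sire_known")
  }
  if (isTRUE(rules$require_sequence)) {
    # iterate lactation order so a removed earlier lactation cascades
    for (l in sort(unique(cl$lactation))) {
      if (l == 1L) next
      prev_ok <- cl$cow[cl$lactation == l - 1L & is.na(fail)]
      cond <- cl$lactation == l & !(cl$cow %in% prev_ok)
      fail <- mark(fail, cond, "sequence")
    }
  }

  failed <- cl[!is.na(fail), c("cow", "lactation")]
  failed$rule <- fail[!is.na(fail)]
  # cow-lactations whose every test was dropped never reach `cl`
  gone <- dplyr::anti_join(raw_counts, cl, by = c("cow", "lactation")) |>
    dplyr::inner_join(first_drop, by = c("cow", "lactation"))
  if (nrow(gone)) {
    failed <- dplyr::bind_rows(
      failed,
      tibble::tibble(cow = gone$cow, lactation = gone$lactation,
                     rule = gone$first_drop_rule))
  }
  for (r in edit_rule_names) cl_removed[r] <- sum(failed$rule == r)

  keep <- dplyr::anti_join(rec, failed, by = c("cow", "lactation"))
  report <- tibble::tibble(
    rule = edit_rule_names,
    td_dropped = as.integer(td_dropped),
    cowlact_removed = as.integer(cl_removed)
  )
  attr(keep, "removal_report") <- report
  keep
}

#' @param edited Result of [apply_edits()].
#' @rdname apply_edits
#' @export
edit_report <- function(edited) {
  rep <- attr(edited, "removal_report")
  if (is.null(rep)) abort("no removal report attached; run apply_edits().")
  rep
}

#' Build fixed-effect codings
#'
#' Adds the fixed-effect classifications of the model to edited records:
#' `htm`, the herd x test-year x test-month contemporary group (shared
#' across lactations); `bsm`, breed group x calving season x
#' stage-of-lactation month within lactation; `age_c`/`age_c2`, age at
#' calving centred within lactation and its square; and `stage`, the
#' stage-of-lactation month.
#'
#' @param records Edited test-day tibble.
#' @return The records with coding columns appended.
#' @export
build_effect_coding <- function(records) {
  rec <- tibble::as_tibble(records)
  rec$stage <- stage_month(rec$dim)
  rec$htm <- level_codes(rec$herd, rec$test_year, rec$test_month)
  rec$bsm <- level_codes(rec$lactation,
                         assign_breed_group(rec$hf_fraction),
                         as.integer(assign_season(rec$calving_month)),
                         rec$stage)
  rec <- rec |>
    dplyr::group_by(.data$lactation) |>
    dplyr::mutate(age_c = .data$age_calving - mean(.data$age_calving),
                  age_c2 = .data$age_c^2 - mean(.data$age_c^2)) |>
    dplyr::ungroup()
  rec
}
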