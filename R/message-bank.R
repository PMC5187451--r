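#' Load a message bank
#'
#' The bank is a CSV with columns `level` (`L0`-`L3` for automated messages,
#' `quit_tips` / `medication_tips` for on-demand menus), `trigger_or_category`
#' (`none`, one of the four Level-2 lapse triggers, or an on-demand category),
#' `message_id`, and `text`. Row order within a slot is the delivery order
#' (Level 0 prequit messages are delivered in this predetermined order).
#'
#' Validation requires every slot the decision engine can reach: all four
#' levels, the four Level-2 triggers (negative affect/stress, urge, cigarette
#' availability, motivation), the five Quit Tips categories and the four
#' medication categories; message ids must be unique.
#'
#' @param path CSV path; `NULL` loads the bundled default bank.
#' @return A `jitai_message_bank` tibble.
#' @examples
#' bank <- default_message_bank()
#' dplyr::count(bank, level)
#' @export
load_message_bank <- function(path = NULL) {
  path <- path %||% system.file("extdata", "message_bank.csv", package = "jitai")
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      level = readr::col_character(),
      trigger_or_category = readr::col_character(),
      message_id = readr::col_character(),
      text = readr::col_character()
    )
  )
  validate_message_bank(df)
}

#' @rdname load_message_bank
#' @export
default_message_bank <- function() load_message_bank(NULL)

TRIGGERS <- c("stress_affect", "urge", "availability", "motivation")

validate_message_bank <- function(df) {
  if (anyDuplicated(df$message_id)) {
    dup <- df$message_id[duplicated(df$message_id)][1]
    abort(paste0("Duplicate message_id in bank: ", dup))
  }
  required <- c(
    paste0("L0", ".", "none"),
    paste0("L1", ".", "none"),
    paste0("L2", ".", TRIGGERS),
    paste0("L3", ".", "none"),
    paste0("quit_tips", ".", QUIT_TIP_CATEGORIES),
    paste0("medication_tips", ".", MEDICATION_CATEGORIES)
  )
  have <- unique(paste0(df$level, ".", df$trigger_or_category))
  missing <- setdiff(required, have)
  if (length(missing)) {
    abort(paste0(
      "Message bank incomplete; missing slot(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  class(df) <- c("jitai_message_bank", class(df))
  df
}

#' Summarise a message bank
#'
#' @param bank A `jitai_message_bank`.
#' @return Tibble of entry counts per (level, trigger_or_category) slot.
#' @export
bank_slot_counts <- function(bank) {
  bank |>
    count(.data$level, .data$trigger_or_category, name = "n_messages") |>
    arrange(.data$level, .data$trigger_or_category)
}

bank_slot <- function(bank, level, trigger_or_category) {
  bank[bank$level == level & bank$trigger_or_category == trigger_or_category, ]
}
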