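## Trial-table schema constants (loaded first; shared by every module).

#' Required columns of a trial table, in canonical order
#'
#' One row per experimental trial. `feedback_time_ms` is an optional extra
#' column accepted on read (the canonical header does not include it).
#'
#' @format character vector of column names.
#' @export
trial_columns <- c(
  "participant_id", "session_index", "phase_type", "phase_index",
  "block_index", "trial_index", "trial_kind", "category", "ground_truth",
  "rating", "viewing_time_ms", "rating_time_ms", "max_viewing_time_ms",
  "feedback_given"
)

phase_types    <- c("pretest", "training", "posttest", "retention")
trial_kinds    <- c("mammogram", "attention", "practice")
categories_all <- c("normal", "obvious", "subtle", "contralateral", "prior",
                    "scene_beach", "scene_forest")
abnormal_categories <- c("obvious", "subtle", "contralateral", "prior")
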