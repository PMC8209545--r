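#' Sample design sheet
#'
#' Validates the per-sample metadata used to build design matrices: which
#' experiment set a library belongs to, its exposure condition, the placenta
#' the trophoblasts were cultured from, and the processing batch (lab).
#'
#' Condition vocabulary: `ctrl_0h` (plating control), `std_48h` (48 h standard
#' culture, the reference level everywhere), `hpx_48h` (48 h hypoxia, allowed
#' only in `hypoxia_set`) and `dmso_48h` (48 h DMSO, allowed only in
#' `dmso_set`).
#'
#' @param df data.frame with columns `sample_id`, `experiment_set`,
#'   `condition`, `placenta_id`, `batch_id`.
#' @return A validated data.frame of class `sample_design`.
#' @export
sample_design <- function(df) {
  required <- c("sample_id", "experiment_set", "condition", "placenta_id", "batch_id")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_validation("design is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[required]
  for (col in required) df[[col]] <- as.character(df[[col]])
  if (nrow(df) == 0L) stop_validation("no samples in design")
  if (anyDuplicated(df$sample_id)) {
    stop_validation("duplicate sample_id(s): ",
                    paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  bad_set <- setdiff(unique(df$experiment_set), EXPERIMENT_SETS)
  if (length(bad_set)) {
    stop_validation("unknown experiment_set token(s): ", paste(bad_set, collapse = ", "))
  }
  bad_cond <- setdiff(unique(df$condition), CONDITIONS)
  if (length(bad_cond)) {
    stop_validation("unknown condition token(s): ", paste(bad_cond, collapse = ", "))
  }
  # exposure conditions are set-specific
  off1 <- df$condition == "hpx_48h" & df$experiment_set != "hypoxia_set"
  off2 <- df$condition == "dmso_48h" & df$experiment_set != "dmso_set"
  if (any(off1 | off2)) {
    stop_validation("exposure condition outside its experiment set for sample(s): ",
                    paste(df$sample_id[off1 | off2], collapse = ", "))
  }
  class(df) <- c("sample_design", "data.frame")
  df
}

#' @rdname sample_design
#' @export
EXPERIMENT_SETS <- c("hypoxia_set", "dmso_set")

#' @rdname sample_design
#' @export
CONDITIONS <- c("ctrl_0h", "std_48h", "hpx_48h", "dmso_48h")

# Check that every sample of a count matrix has exactly one design row and
# return the design reordered to match the matrix columns.
align_design <- function(counts, design) {
  missing_s <- setdiff(sample_ids(counts), design$sample_id)
  if (length(missing_s)) {
    stop_validation("samples without a design row: ", paste(missing_s, collapse = ", "))
  }
  out <- design[match(sample_ids(counts), design$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sample_design", "data.frame")
  out
}
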