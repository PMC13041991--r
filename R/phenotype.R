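#' Sensory Subset Score (SSS)
#'
#' Sum of three sensory-related social-responsiveness items (each coded
#' 0 = No/Not True, 1 = Sometimes True, 2 = Often True, 3 = Almost Always
#' True) and one binary communication-questionnaire item coded Yes = 3 /
#' No = 0, giving a composite from 0 to 12. Any missing item makes the score
#' missing; no partial sums are formed.
#'
#' @param item20,item42,item58 Ordinal item responses in `{0, 1, 2, 3}`.
#' @param scq14 `"Yes"`/`"No"`, logical, or already-coded `{0, 3}`.
#' @return Integer score in `[0, 12]` (vectorized; `NA` where any item is
#'   missing).
#' @export
sensory_subset_score <- function(item20, item42, item58, scq14) {
  check_item <- function(x, nm) {
    bad <- !is.na(x) & !(x %in% 0:3)
    if (any(bad)) stop(sprintf("%s out of range {0,1,2,3}: %s", nm,
                               paste(unique(x[bad]), collapse = ", ")))
    x
  }
  item20 <- check_item(item20, "item20")
  item42 <- check_item(item42, "item42")
  item58 <- check_item(item58, "item58")
  scq <- if (is.character(scq14) || is.logical(scq14)) {
    s <- ifelse(is.na(scq14), NA_real_,
                ifelse(scq14 == "Yes" | scq14 == TRUE, 3,
                       ifelse(scq14 == "No" | scq14 == FALSE, 0, NaN)))
    if (any(is.nan(s))) stop("scq14 must be Yes/No (or coded 0/3)")
    s
  } else {
    bad <- !is.na(scq14) & !(scq14 %in% c(0, 3))
    if (any(bad)) stop("coded scq14 must be 0 or 3")
    as.numeric(scq14)
  }
  as.integer(item20 + item42 + item58 + scq)
}

#' Assign diagnostic analysis groups from consensus labels
#'
#' Maps clinician consensus labels to analysis groups: 'Autism Spectrum
#' Disorder' to `ASD`, 'No Diagnosis Given' to `nonASD`; incomplete or
#' unexplained no-diagnosis labels (and anything unrecognized, including
#' empty labels) to `excluded` with a logged reason. Co-occurring ADHD never
#' excludes a subject from the ASD group; it sets the `adhd` flag, from which
#' the strata `ASD+ADHD` / `ASD-ADHD` / `nonASD` are derived.
#'
#' @param records Data frame with columns `consensus_label` and (optionally)
#'   `adhd` (logical or 0/1).
#' @return The input with columns `group` (`ASD`/`nonASD`/`excluded`),
#'   `adhd`, `adhd_stratum`, and `exclusion_reason` appended.
#' @export
assign_groups <- function(records) {
  stopifnot("consensus_label" %in% names(records))
  lab <- trimws(as.character(records$consensus_label))
  adhd <- if ("adhd" %in% names(records)) {
    as.logical(records$adhd) %in% TRUE
  } else rep(FALSE, nrow(records))
  group <- rep("excluded", length(lab))
  reason <- rep(NA_character_, length(lab))
  group[lab == "Autism Spectrum Disorder"] <- "ASD"
  group[lab == "No Diagnosis Given"] <- "nonASD"
  drop_labels <- c("No Diagnosis Given: Incomplete Eval",
                   "No Diagnosis Given: No Reason Given")
  reason[lab %in% drop_labels] <- "incomplete or unexplained evaluation"
  unknown <- group == "excluded" & !(lab %in% drop_labels)
  reason[unknown] <- ifelse(lab[unknown] == "",
                            "empty consensus label",
                            paste("unrecognized label:", lab[unknown]))
  adhd[group == "nonASD"] <- FALSE
  stratum <- ifelse(group == "ASD" & adhd, "ASD+ADHD",
                    ifelse(group == "ASD", "ASD-ADHD",
                           ifelse(group == "nonASD", "nonASD",
                                  NA_character_)))
  records$group <- group
  records$adhd <- adhd
  records$adhd_stratum <- stratum
  records$exclusion_reason <- reason
  records
}
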