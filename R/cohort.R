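#' Volume-weighted bilateral average of two muscle feature sets
#'
#' Combines the right and left feature rows of one muscle group into a
#' bilateral row: every feature (mean PDFF and all 11 texture features) is
#' averaged with weights equal to the physical muscle volumes,
#' `f = (f_R * V_R + f_L * V_L) / (V_R + V_L)`, and the volumes add.
#'
#' @param right,left One-row tibbles from [texture_profile()] for the same
#'   muscle, opposite sides, both with positive volume.
#' @return A one-row tibble with `side = "bilateral"`.
#' @export
bilateral_average <- function(right, left) {
  if (!identical(right$muscle, left$muscle)) {
    stop_pdff("bilateral averaging requires the same muscle group.",
              "pdff_domain_error")
  }
  if (identical(right$side, left$side)) {
    stop_pdff("bilateral averaging requires opposite sides.",
              "pdff_domain_error")
  }
  vr <- right$volume_mm3
  vl <- left$volume_mm3
  if (!isTRUE(vr > 0) || !isTRUE(vl > 0)) {
    stop_pdff("both sides must have positive physical volume.",
              "pdff_domain_error")
  }
  wcols <- c("mean_pdff", feature_names())
  out <- right
  out$side <- "bilateral"
  for (cl in wcols) {
    out[[cl]] <- (right[[cl]] * vr + left[[cl]] * vl) / (vr + vl)
  }
  out$volume_mm3 <- vr + vl
  out$voxel_count <- right$voxel_count + left$voxel_count
  out$degenerate <- right$degenerate | left$degenerate
  out$n_skipped_directions <- right$n_skipped_directions +
    left$n_skipped_directions
  out
}

#' Bilateral aggregation of a per-muscle feature table
#'
#' Data-frame verb form of [bilateral_average()]: takes the 4-row
#' right/left x ES/PS table of one subject and returns one bilateral row
#' per muscle group.
#'
#' @param features Tibble of [texture_profile()] rows with both sides of
#'   each muscle present.
#' @return Tibble with one row per muscle.
#' @export
aggregate_bilateral <- function(features) {
  dplyr::group_split(dplyr::group_by(features, .data$muscle)) |>
    purrr::map(function(df) {
      if (nrow(df) != 2L) {
        stop_pdff("each muscle needs exactly one right and one left row.",
                  "pdff_schema_error")
      }
      bilateral_average(df[df$side == "right", ], df[df$side == "left", ])
    }) |>
    dplyr::bind_rows()
}

#' Candidate predictor columns of the cohort table
#'
#' Age, BMI, the two bilateral mean PDFF values and the 22 bilateral texture
#' features (11 per muscle group): 26 candidates in total.
#'
#' @return Character vector of length 26.
#' @export
cohort_predictors <- function() {
  c("age", "bmi", "pdff_es", "pdff_ps",
    paste0(feature_names(), "_es"), paste0(feature_names(), "_ps"))
}

#' Assemble the per-subject cohort table
#'
#' Flattens a list of subject records into one analysis-ready tibble: one
#' row per subject with `subject_id`, `sex`, the 26 candidate predictors of
#' [cohort_predictors()] and the two strength outcomes (`mvic_ext`,
#' `mvic_flex`, in Nm). The column census is validated.
#'
#' @param records List of subject records; each is a list with
#'   `subject_id`, `sex` (`"male"`/`"female"`), `age`, `bmi`, `features`
#'   (the 4-row per-muscle [texture_profile()] table or a 2-row bilateral
#'   table), `mvic_ext`, `mvic_flex`.
#' @return A tibble with `2 + 26 + 2` columns and one row per subject.
#' @export
build_cohort_table <- function(records) {
  if (length(records) < 2L) {
    stop_pdff("need at least 2 subject records.", "pdff_schema_error")
  }
  ids <- vapply(records, function(r) as.character(r$subject_id), character(1))
  if (anyDuplicated(ids)) {
    stop_pdff("subject ids must be unique.", "pdff_schema_error")
  }
  rows <- purrr::map(records, function(r) {
    feats <- r$features
    if (!all(c("ES", "PS") %in% feats$muscle)) {
      stop_pdff("each subject needs ES and PS feature sets.",
                "pdff_schema_error")
    }
    if (any(feats$side != "bilateral")) feats <- aggregate_bilateral(feats)
    wide <- list(subject_id = as.character(r$subject_id), sex = r$sex,
                 age = r$age, bmi = r$bmi)
    for (mg in c("ES", "PS")) {
      row <- feats[feats$muscle == mg, ]
      suffix <- tolower(mg)
      wide[[paste0("pdff_", suffix)]] <- row$mean_pdff
      for (f in feature_names()) {
        v <- row[[f]]
        if (is.null(v) || is.na(v)) {
          stop_pdff(paste0("missing feature ", f, " for ", mg, "."),
                    "pdff_schema_error")
        }
        wide[[paste0(f, "_", suffix)]] <- v
      }
    }
    wide$mvic_ext <- r$mvic_ext
    wide$mvic_flex <- r$mvic_flex
    as_tibble(wide)
  })
  out <- dplyr::bind_rows(rows)
  stopifnot(all(cohort_predictors() %in% names(out)))
  out
}
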