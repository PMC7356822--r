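# ROI statistics and the thalamus-standardized contrast-to-noise ratio.
# The thalamus serves as the intensity-standardization region: every other
# region's contrast is expressed in units of thalamic signal variability,
# which makes the CNR exactly invariant under positive affine intensity
# transforms of the whole image.

#' ROI statistics for one label
#'
#' Mean, sample standard deviation (n - 1 denominator) and voxel count over
#' exactly the voxels carrying `label_id`.
#'
#' @param image Numeric array.
#' @param labelmap Integer array on the same grid.
#' @param label_id Label to extract; must be present.
#' @return A list of class `roi_stats`: `label`, `mean`, `sd`, `n`.
#' @export
roi_stats <- function(image, labelmap, label_id) {
  if (!identical(dim(image), dim(labelmap)))
    stop_synthmri("image and labelmap are not on the same grid",
                  "grid_mismatch")
  v <- image[labelmap == label_id]
  if (!length(v))
    stop_synthmri(sprintf("label %s absent from label map",
                          format(label_id)), "missing_label")
  structure(list(label = label_id, mean = mean(v),
                 sd = if (length(v) > 1L) sd(v) else 0,
                 n = length(v)),
            class = "roi_stats")
}

#' Thalamus-standardized contrast-to-noise ratio
#'
#' `CNR = (mean(region) - mean(thalamus)) / sd(thalamus)`: the signed
#' contrast of a region against the thalamus in units of thalamic
#' variability. Noiseless input (thalamus sd 0) is an error by contract —
#' the ratio would be infinite and meaningless.
#'
#' @param region `roi_stats` of the region of interest.
#' @param thalamus `roi_stats` of the thalamus.
#' @return Signed dimensionless CNR.
#' @export
standardized_cnr <- function(region, thalamus) {
  if (!inherits(region, "roi_stats") || !inherits(thalamus, "roi_stats"))
    stop_synthmri("arguments must be roi_stats objects", "invalid_roi")
  if (thalamus$sd <= 0)
    stop_synthmri("thalamus sd is 0: noiseless input has no defined CNR",
                  "zero_noise")
  (region$mean - thalamus$mean) / thalamus$sd
}

#' CNR of several regions of one image
#'
#' @param image Numeric array.
#' @param labelmap Integer label array on the same grid.
#' @param region_ids Named integer vector of region labels.
#' @param thalamus_id Label of the standardization region.
#' @return Named numeric vector of CNRs, one per region.
#' @export
cnr_by_region <- function(image, labelmap, region_ids, thalamus_id) {
  thal <- roi_stats(image, labelmap, thalamus_id)
  vapply(region_ids, function(id)
    standardized_cnr(roi_stats(image, labelmap, id), thal), numeric(1))
}

#' Compare CNR between acquisition modes across a matched cohort
#'
#' For every (region, contrast) cell, the per-subject CNR values of all
#' modes form a Friedman design (subjects as blocks, modes as treatments);
#' p-values are Bonferroni-corrected over the whole region-by-contrast
#' family. Subjects must be identical across modes (matched design).
#'
#' @param cnr_data Data.frame with columns `subject`, `mode`, `region`,
#'   `contrast`, `cnr`; one row per combination.
#' @param alpha Family-wise significance level.
#' @return A list of class `cnr_report`: `tests` (data.frame with mean
#'   per-mode CNR, mean paired difference, `p`, `p_adjusted`, `reject`),
#'   `alpha`, `n_subjects`, `modes`.
#' @export
compare_modes <- function(cnr_data, alpha = 0.05) {
  need <- c("subject", "mode", "region", "contrast", "cnr")
  if (!all(need %in% names(cnr_data)))
    stop_synthmri(paste("cnr_data needs columns:",
                        paste(need, collapse = ", ")), "invalid_table")
  modes <- sort(unique(as.character(cnr_data$mode)))
  if (length(modes) < 2L)
    stop_synthmri("need >= 2 modes to compare", "invalid_design")
  subj_by_mode <- lapply(modes, function(m)
    sort(unique(cnr_data$subject[cnr_data$mode == m])))
  if (!all(vapply(subj_by_mode, identical, logical(1), subj_by_mode[[1]])))
    stop_synthmri("subject sets differ between modes (unmatched design)",
                  "unmatched_subjects")
  subjects <- subj_by_mode[[1]]

  cells <- unique(cnr_data[, c("region", "contrast")])
  cells <- cells[order(cells$region, cells$contrast), , drop = FALSE]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- cnr_data$region == cells$region[i] &
      cnr_data$contrast == cells$contrast[i]
    d <- cnr_data[sel, ]
    m <- vapply(modes, function(md) {
      v <- d$cnr[d$mode == md][match(subjects, d$subject[d$mode == md])]
      if (length(v) != length(subjects) || any(is.na(v)))
        stop_synthmri(sprintf(
          "incomplete CNR data for region %s, contrast %s, mode %s",
          cells$region[i], cells$contrast[i], md), "invalid_table")
      v
    }, numeric(length(subjects)))
    p <- friedman_test(m)$p_value
    out <- data.frame(region = cells$region[i],
                      contrast = cells$contrast[i],
                      stringsAsFactors = FALSE)
    for (md in modes) out[[paste0("mean_cnr_", md)]] <- mean(m[, md])
    out$mean_paired_diff <- mean(m[, modes[2]] - m[, modes[1]])
    out$p <- p
    out
  })
  tests <- do.call(rbind, rows)
  adj <- bonferroni(tests$p, alpha)
  tests$p_adjusted <- adj$p_adjusted
  tests$reject <- adj$reject
  structure(list(tests = tests, alpha = alpha,
                 n_subjects = length(subjects), modes = modes),
            class = "cnr_report")
}

#' @export
print.cnr_report <- function(x, ...) {
  cat(sprintf("<cnr_report> %d subjects, modes: %s\n", x$n_subjects,
              paste(x$modes, collapse = " vs ")))
  print(x$tests, digits = 4, row.names = FALSE)
  invisible(x)
}
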