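## Diameter sweep: which fixed internal lumen diameter yields the most
## assessable wall measurements (highest cumulative APF) across the lung.

#' Cumulative-APF sweep over candidate internal diameters
#'
#' For each candidate diameter, fixed-diameter locations are selected
#' per subject (same tolerance and APF rule as the main measurement) and
#' their local APFs summed; subject sums are averaged per group and
#' overall. The optimal diameter maximizes the grand mean; ties resolve
#' to the smaller diameter (closer to the flow-limiting periphery).
#'
#' @param subjects List of per-subject location tables (data.frames from
#'   [measure_airways()]), or a single table.
#' @param candidates Candidate internal diameters, mm (default the
#'   2.5-5.0 mm grid).
#' @param tol_mm Diameter tolerance, mm.
#' @param min_apf Minimum local APF for inclusion.
#' @param groups Optional per-subject group labels (e.g. normal /
#'   emphysema / obstructed strata).
#' @return A `sweep_result`: `diameters_mm`, `apf_cum` (subject x
#'   candidate matrix), `group_means`, `grand_mean`, `optimal_mm`.
#' @export
apf_sweep <- function(subjects, candidates = c(2.5, 3, 3.5, 4, 4.5, 5),
                      tol_mm = 0.25, min_apf = 0.25, groups = NULL) {
  if (is.data.frame(subjects)) subjects <- list(subjects)
  if (length(subjects) < 1 || length(candidates) < 1) {
    stop_domain("need at least one subject and one candidate")
  }
  candidates <- sort(candidates)
  apf_cum <- t(vapply(subjects, function(locs) {
    vapply(candidates, function(d) {
      sel <- select_fixed_diameter_locations(locs, d, tol_mm, min_apf)
      sum(sel$apf_local)
    }, numeric(1))
  }, numeric(length(candidates))))
  colnames(apf_cum) <- sprintf("%.2f", candidates)
  grand <- colMeans(apf_cum)
  group_means <- NULL
  if (!is.null(groups)) {
    group_means <- do.call(rbind, lapply(split(seq_along(subjects), groups),
                                         function(i) {
      colMeans(apf_cum[i, , drop = FALSE])
    }))
  }
  best <- which(grand == max(grand))[1]  # ties -> smaller diameter
  structure(
    list(diameters_mm = candidates, apf_cum = apf_cum,
         group_means = group_means, grand_mean = grand,
         optimal_mm = candidates[best]),
    class = "sweep_result"
  )
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("APF sweep over internal diameters (mm):\n")
  print(round(x$grand_mean, 1))
  cat(sprintf("optimal diameter: %.2f mm\n", x$optimal_mm))
  invisible(x)
}
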