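#' Run the full wild-type versus variant comparison
#'
#' Orchestrates the whole comparative workflow over a set of trajectories
#' sharing a topology: per-protein summary means (RMSD and Rg) with
#' percent differences from the wild type, KDE distributions, dynamic
#' cross-correlation category fractions, dynamic residue network averages,
#' and per-variant WT-minus-variant delta profiles (RMSF, averaged L,
#' averaged BC) with two-standard-deviation outlier reports. All stages
#' are deterministic given the inputs.
#'
#' @param trajectories Named list of [trajectory()] objects (names are the
#'   protein labels), or of file paths read via [read_multimodel_pdb()].
#' @param wt_label Label of the wild type; must be one of the names.
#' @param selection Selection for RMSD/Rg/RMSF/DCC (default `"CA"`).
#' @param cutoff Contact cutoff in Angstrom for the residue networks.
#' @param stride,interval_ps Network frame sampling, see
#'   [network_timeseries()].
#' @param dcc_thresholds Cut points for [classify_motion()].
#' @param sd_k Outlier threshold multiplier for [select_outliers()].
#' @param kde_bandwidth Optional KDE bandwidth override.
#' @param timestep_ps Timestep applied when reading trajectories from
#'   paths.
#' @param output_dir Optional directory; when given, CSV/JSON artefacts
#'   are written there (`summary.csv`, `kde_<label>.csv`,
#'   `dcc_<label>.csv`, `drn_<label>.csv`, `delta_<variant>_<metric>.csv`,
#'   `outliers_<variant>.json`, `report.json`).
#' @return A `comparison_report` list with elements `summary`
#'   (RMSD + Rg summary table), `kde`, `dcc_fractions`, `drn`, `delta`
#'   and `outliers` (per variant, per metric), and `config`.
#' @export
run_comparison <- function(trajectories, wt_label = "WT", selection = "CA",
                           cutoff = 6.7, stride = 1L, interval_ps = NULL,
                           dcc_thresholds = c(-0.25, 0.25), sd_k = 2.0,
                           kde_bandwidth = NULL, timestep_ps = NULL,
                           output_dir = NULL) {
  if (is.null(names(trajectories)) || any(!nzchar(names(trajectories)))) {
    stop("trajectories must be a named list (one label per protein)")
  }
  if (anyDuplicated(names(trajectories))) stop("duplicate protein labels")
  if (!wt_label %in% names(trajectories)) {
    stop("wt_label '", wt_label, "' not among trajectory labels")
  }
  trajectories <- lapply(names(trajectories), function(lb) {
    tr <- trajectories[[lb]]
    if (is.character(tr)) {
      tr <- read_multimodel_pdb(tr, label = lb, timestep_ps = timestep_ps)
    }
    tr$label <- lb
    tr
  })
  names(trajectories) <- vapply(trajectories, `[[`, "", "label")
  labels <- names(trajectories)
  variants <- setdiff(labels, wt_label)

  # comparable topologies across proteins
  wt <- trajectories[[wt_label]]
  for (lb in variants) {
    tv <- trajectories[[lb]]
    if (n_residues(tv) != n_residues(wt)) {
      stop("topology mismatch for ", lb, ": ", n_residues(tv),
           " residues vs ", n_residues(wt), " in ", wt_label)
    }
    diff <- which(tv$residues$residue_number != wt$residues$residue_number)
    if (length(diff)) {
      stop("topology mismatch for ", lb, ": residue numbering differs ",
           "first at position ", diff[1])
    }
  }

  rmsd <- lapply(trajectories, rmsd_series, selection = selection)
  rg <- lapply(trajectories, rg_series, selection = selection)
  summary_df <- rbind(summary_table(unname(rmsd), wt_label),
                      summary_table(unname(rg), wt_label))
  class(summary_df) <- c("summary_table", "data.frame")

  kde <- lapply(rmsd, kde_distribution, bandwidth = kde_bandwidth)

  dcc_fractions <- lapply(trajectories, function(tr) {
    classify_motion(dcc_matrix(tr, selection = selection),
                    thresholds = dcc_thresholds)$fractions
  })

  rmsf <- lapply(trajectories, rmsf_profile, selection = selection)
  drn <- lapply(trajectories, function(tr) {
    average_profiles(network_timeseries(tr, cutoff = cutoff, stride = stride,
                                        interval_ps = interval_ps))
  })

  delta <- list()
  outliers <- list()
  for (lb in variants) {
    d_rmsf <- delta_profile(rmsf[[wt_label]], rmsf[[lb]])
    d_L <- delta_profile(network_profile(drn[[wt_label]], "avgL"),
                         network_profile(drn[[lb]], "avgL"))
    d_BC <- delta_profile(network_profile(drn[[wt_label]], "avgBC"),
                          network_profile(drn[[lb]], "avgBC"))
    delta[[lb]] <- list(deltaRMSF = d_rmsf, deltaL = d_L, deltaBC = d_BC)
    outliers[[lb]] <- list(deltaRMSF = select_outliers(d_rmsf, k = sd_k),
                           deltaL = select_outliers(d_L, k = sd_k),
                           deltaBC = select_outliers(d_BC, k = sd_k))
  }

  report <- structure(list(
    summary = summary_df,
    kde = kde,
    dcc_fractions = dcc_fractions,
    drn = drn,
    rmsf = rmsf,
    delta = delta,
    outliers = outliers,
    config = list(wt_label = wt_label, labels = labels,
                  selection = selection, cutoff = cutoff, stride = stride,
                  interval_ps = interval_ps, dcc_thresholds = dcc_thresholds,
                  sd_k = sd_k)
  ), class = "comparison_report")
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

#' Write report artefacts to a directory
#'
#' @param report A `comparison_report`.
#' @param output_dir Directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(output_dir, ...)
  utils::write.csv(report$summary, p("summary.csv"), row.names = FALSE)
  for (lb in names(report$kde)) {
    k <- report$kde[[lb]]
    utils::write.csv(data.frame(grid = k$grid, density = k$density),
                     p(paste0("kde_", lb, ".csv")), row.names = FALSE)
  }
  for (lb in names(report$dcc_fractions)) {
    utils::write.csv(data.frame(category = names(report$dcc_fractions[[lb]]),
                                fraction = as.numeric(report$dcc_fractions[[lb]])),
                     p(paste0("dcc_", lb, ".csv")), row.names = FALSE)
  }
  for (lb in names(report$drn)) {
    a <- report$drn[[lb]]
    utils::write.csv(data.frame(residue_label = a$labels,
                                avg_L = a$avg_L_normalized,
                                avg_BC = a$avg_BC_normalized,
                                avg_BC_raw = a$avg_BC_raw,
                                missing = a$missing_counts),
                     p(paste0("drn_", lb, ".csv")), row.names = FALSE)
  }
  for (lb in names(report$delta)) {
    for (m in names(report$delta[[lb]])) {
      utils::write.csv(as.data.frame(report$delta[[lb]][[m]]),
                       p(paste0("delta_", lb, "_", m, ".csv")),
                       row.names = FALSE)
    }
    ol <- lapply(report$outliers[[lb]], function(o) {
      o[c("metric", "increase", "decrease", "mean", "sd", "k", "note")]
    })
    jsonlite::write_json(ol, p(paste0("outliers_", lb, ".json")),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  jsonlite::write_json(report_as_list(report), p("report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(output_dir)
}

# JSON-serializable view of a report (used for report.json).
report_as_list <- function(report) {
  list(
    config = report$config,
    summary = report$summary,
    dcc_fractions = lapply(report$dcc_fractions, as.list),
    outliers = lapply(report$outliers, function(per_metric) {
      lapply(per_metric, function(o) {
        o[c("metric", "increase", "decrease", "mean", "sd", "k", "note")]
      })
    })
  )
}

#' Render fixed-width text tables from a comparison report
#'
#' Produces a mean/percent-difference table (one block per metric, WT row
#' printing a 0.00 percent difference) and a four-quadrant outlier table
#' per variant (accessibility increase/decrease from delta-L,
#' communication reduction/increase from delta-BC), with `-` marking
#' empty quadrants.
#'
#' @param report A `comparison_report`.
#' @return Character vector of lines (printable with `cat(..., sep =
#'   "\n")`).
#' @export
render_tables <- function(report) {
  lines <- character(0)
  add <- function(...) lines <<- c(lines, ...)
  s <- report$summary
  for (m in unique(s$metric)) {
    add(sprintf("Mean %s and percent difference from %s", m,
                report$config$wt_label))
    w <- max(10L, nchar(s$label))
    add(sprintf("%-*s %10s %12s", w, "Protein", "Mean", "% Diff"))
    b <- s[s$metric == m, ]
    for (i in seq_len(nrow(b))) {
      add(sprintf("%-*s %10.3f %12.2f", w, b$label[i],
                  round_half_up(b$mean[i], 3),
                  round_half_up(b$pct_diff_from_wt[i], 2)))
    }
    add("")
  }
  fmt <- function(v) if (length(v)) paste(v, collapse = " ") else "-"
  for (lb in names(report$outliers)) {
    o <- report$outliers[[lb]]
    add(sprintf("Variant %s: residue network changes (k = %g SD)", lb,
                report$config$sd_k))
    add(sprintf("  Accessibility increase (positive dL):  %s",
                fmt(o$deltaL$increase)))
    add(sprintf("  Accessibility decrease (negative dL):  %s",
                fmt(o$deltaL$decrease)))
    add(sprintf("  Communication reduction (positive dBC): %s",
                fmt(o$deltaBC$increase)))
    add(sprintf("  Communication increase (negative dBC): %s",
                fmt(o$deltaBC$decrease)))
    add("")
  }
  lines
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(render_tables(x), sep = "\n")
  invisible(x)
}
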