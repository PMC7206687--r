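## End-to-end orchestration: simulate -> fit -> assess -> endpoints,
## with CSV/JSON report output and publication-style table formatting.

## rbind a list of data.frame rows; NULL (not FALSE) when the list is empty
rbind_rows <- function(rows) {
  if (!length(rows)) return(NULL)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Per-animal kinetic endpoints for a cohort
#'
#' For every animal with an observed treatment-day volume, computes the
#' pre- and post-treatment doubling times (from daily Hermite interpolants
#' of each window), the post-treatment regression percentage and minimum
#' volume, and the response class (controls get doubling times only).
#'
#' @param cohort result of [simulate_cohort()] or a long-format table.
#' @param design the [study_design()].
#' @param thresholds response thresholds, see [classify_response()].
#' @param min_points minimum observations per window for an endpoint.
#' @return data.frame, one row per animal.
#' @export
endpoint_table <- function(cohort, design,
                           thresholds = list(cr_volume = 0.01,
                                             pr_regression = 50,
                                             pd_growth = 2,
                                             pd_max_regression = 25),
                           min_points = 3) {
  tab <- if (is.data.frame(cohort)) cohort else cohort$table
  stopifnot(inherits(design, "study_design"))
  td <- design$treatment_day
  groups <- design$groups
  rows <- list()
  for (id in unique(tab$animal_id)) {
    ser <- tab[tab$animal_id == id, ]
    grp <- ser$group[1]
    i_app <- groups$i[groups$group == grp]
    pre <- ser[ser$day <= td, ]
    post <- ser[ser$day >= td, ]
    if (!(td %in% ser$day)) next
    V_td <- ser$volume_cm3[ser$day == td][1]

    dt_pre <- dt_post <- NA_real_
    if (nrow(pre) >= min_points) {
      cv <- hermite_interpolate(pre$day, pre$volume_cm3)
      dt_pre <- doubling_time_from_data(cv)
    }
    if (nrow(post) >= min_points) {
      cv <- hermite_interpolate(post$day, post$volume_cm3)
      dt_post <- doubling_time_from_data(cv, V0 = V_td)
    }
    resp <- reg <- vmin <- NA
    if (i_app > 0 && nrow(post) >= 1) {
      cls <- classify_response(post, V_td, thresholds)
      resp <- cls$response
      reg <- cls$regression$regression_percent
      vmin <- cls$regression$Vmin
    }
    rows[[id]] <- data.frame(
      animal_id = id, group = grp, gender = ser$gender[1],
      V_treatment = V_td,
      doubling_time_pre = dt_pre, doubling_time_post = dt_post,
      regression_percent = reg, Vmin = vmin,
      response = as.character(resp), stringsAsFactors = FALSE)
  }
  rbind_rows(rows)
}

## control group paired with a treated group: matched electrode geometry
paired_control <- function(group, groups) {
  geom <- groups$geometry[groups$group == group]
  ctrl <- groups$group[groups$control & groups$geometry == geom]
  if (!length(ctrl)) ctrl <- groups$group[groups$control][1]
  ctrl[1]
}

#' Group-level endpoint summaries
#'
#' Aggregates [endpoint_table()] rows into a response-count table
#' (PD/SD/PR/CR tallies with percentages and overall effectiveness per
#' treated group and gender), a doubling-time table (mean +/- SEM before
#' and after treatment for every group), and growth delays of each treated
#' group relative to its geometry-matched control group.
#'
#' @param ep result of [endpoint_table()].
#' @param design the [study_design()].
#' @return list with `responses`, `doubling_times`, `growth_delay`
#'   data.frames.
#' @export
endpoint_summary <- function(ep, design) {
  groups <- design$groups
  resp_rows <- dt_rows <- gd_rows <- list()
  for (grp in unique(ep$group)) {
    for (gender in unique(ep$gender[ep$group == grp])) {
      sub <- ep[ep$group == grp & ep$gender == gender, ]
      key <- paste(grp, gender)
      dt_rows[[key]] <- data.frame(
        group = grp, gender = gender, n = nrow(sub),
        dt_pre_mean = mean(sub$doubling_time_pre[is.finite(sub$doubling_time_pre)]),
        dt_pre_sem = sem(sub$doubling_time_pre),
        dt_post_mean = mean(sub$doubling_time_post[is.finite(sub$doubling_time_post)]),
        dt_post_sem = sem(sub$doubling_time_post),
        stringsAsFactors = FALSE)
      if (!groups$control[groups$group == grp]) {
        cls <- sub$response[!is.na(sub$response)]
        n <- length(cls)
        counts <- vapply(c("PD", "SD", "PR", "CR"),
                         function(x) sum(cls == x), integer(1))
        resp_rows[[key]] <- data.frame(
          group = grp, gender = gender, n = n,
          PD = counts[["PD"]], SD = counts[["SD"]],
          PR = counts[["PR"]], CR = counts[["CR"]],
          effectiveness = if (n) overall_effectiveness(cls) else NA_real_,
          stringsAsFactors = FALSE)
        ctrl <- paired_control(grp, groups)
        csub <- ep[ep$group == ctrl & ep$gender == gender, ]
        gd <- if (nrow(csub)) {
          tryCatch(suppressWarnings(
            growth_delay(sub$doubling_time_post, csub$doubling_time_post)),
            error = function(e) NA_real_)
        } else NA_real_
        gd_rows[[key]] <- data.frame(group = grp, gender = gender,
                                     control = ctrl, growth_delay = gd,
                                     stringsAsFactors = FALSE)
      }
    }
  }
  list(responses = rbind_rows(resp_rows),
       doubling_times = rbind_rows(dt_rows),
       growth_delay = rbind_rows(gd_rows))
}

#' Run the whole analysis pipeline
#'
#' Simulates a cohort under the design, fits the two-stage protocol with
#' assessment diagnostics, computes endpoints and group summaries, and
#' (optionally) writes every table plus a resolved-configuration snapshot
#' to a directory. Deterministic given the design seed.
#'
#' @param design a [study_design()] (carries the mandatory seed).
#' @param hyper hyperparameters from [default_hyperparams()].
#' @param out_dir optional output directory for CSV/JSON reports.
#' @param diagnostics,press_mode,ratio_mode passed to [fit_pipeline()].
#' @param thresholds passed to [endpoint_table()].
#' @param cap_per_group passed to [fit_pipeline()].
#' @return (invisibly) list with `cohort`, `fits`, `endpoints`,
#'   `endpoint_summary`, `config`.
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(study_design(seed = 7))
#' res$fits$summary[res$fits$summary$stage == "TGK2", c("group", "gender", "ratio")]
#' }
run_pipeline <- function(design, hyper = default_hyperparams(),
                         out_dir = NULL, diagnostics = TRUE,
                         press_mode = "printed",
                         ratio_mode = "ratio_of_means",
                         thresholds = list(cr_volume = 0.01,
                                           pr_regression = 50,
                                           pd_growth = 2,
                                           pd_max_regression = 25),
                         cap_per_group = Inf) {
  stopifnot(inherits(design, "study_design"))
  cohort <- simulate_cohort(design, hyper)
  fits <- fit_pipeline(cohort, design, censor_volume = hyper$censor_volume,
                       diagnostics = diagnostics, press_mode = press_mode,
                       ratio_mode = ratio_mode, cap_per_group = cap_per_group)
  ep <- endpoint_table(cohort, design, thresholds = thresholds)
  eps <- endpoint_summary(ep, design)
  config <- list(
    seed = design$seed, treatment_day = design$treatment_day,
    last_day = design$last_day, measurement_days = design$measurement_days,
    noise_cv = hyper$noise_cv, cv = hyper$cv,
    hazard_pre = hyper$hazard_pre, p_death_post = hyper$p_death_post,
    frac_death_early = hyper$frac_death_early,
    censor_volume = hyper$censor_volume,
    press_mode = press_mode, ratio_mode = ratio_mode,
    thresholds = thresholds, cap_per_group = cap_per_group
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cohort$table, file.path(out_dir, "cohort.csv"),
                     row.names = FALSE)
    utils::write.csv(design$groups, file.path(out_dir, "design_groups.csv"),
                     row.names = FALSE)
    utils::write.csv(fits$animal_table, file.path(out_dir, "animal_fits.csv"),
                     row.names = FALSE)
    utils::write.csv(fits$summary, file.path(out_dir, "group_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(ep, file.path(out_dir, "endpoints_animal.csv"),
                     row.names = FALSE)
    utils::write.csv(eps$responses, file.path(out_dir, "response_table.csv"),
                     row.names = FALSE)
    utils::write.csv(eps$doubling_times,
                     file.path(out_dir, "doubling_table.csv"),
                     row.names = FALSE)
    utils::write.csv(eps$growth_delay, file.path(out_dir, "growth_delay.csv"),
                     row.names = FALSE)
    jsonlite::write_json(config, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(cohort = cohort, fits = fits, endpoints = ep,
                 endpoint_summary = eps, config = config))
}

#' Publication-style mean +/- SEM table
#'
#' Formats a group-summary data.frame (as produced by [fit_pipeline()])
#' into `"x.xxx ± y.yyy"` cells; ratio columns are printed to 3
#' decimals. Groups with a single animal get a blank SEM flag.
#'
#' @param summary a summary data.frame with `<col>_mean` / `<col>_sem`
#'   pairs.
#' @param cols which statistics to include (bare names, e.g. `"alpha"`).
#' @param digits decimals for the mean and SEM.
#' @return data.frame of formatted character cells, keyed by group, gender
#'   and stage.
#' @export
format_group_table <- function(summary,
                               cols = c("alpha", "beta", "SSE", "SE", "ra2",
                                        "PRESS", "MPRESS", "RMSE", "Dmax"),
                               digits = 3) {
  out <- summary[, intersect(c("group", "gender", "stage", "n"),
                             names(summary)), drop = FALSE]
  fmt <- function(m, s) {
    ifelse(is.na(m), "NA",
           ifelse(is.na(s),
                  sprintf(paste0("%.", digits, "f ± —"), m),
                  sprintf(paste0("%.", digits, "f ± %.", digits, "f"),
                          m, s)))
  }
  for (cc in cols) {
    mcol <- paste0(cc, "_mean"); scol <- paste0(cc, "_sem")
    if (!mcol %in% names(summary)) {
      warning("column ", cc, " missing from summary; NA cells emitted")
      out[[cc]] <- "NA"
      next
    }
    out[[cc]] <- fmt(summary[[mcol]], summary[[scol]])
  }
  if ("ratio" %in% names(summary)) {
    out$ratio <- ifelse(is.na(summary$ratio), "",
                        sprintf("%.3f", summary$ratio))
  }
  out
}
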