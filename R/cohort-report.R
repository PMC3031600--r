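# Full-cohort experiment orchestration: simulate both treatment arms for
# every modality, run the corresponding analysis pipeline, and emit summary
# tables (mean +/- SEM per arm with the matching statistical test), all
# reproducible from config + seed.

#' Default two-arm experiment configuration
#'
#' Encodes the emulated study design: a saline and a dexamethasone-like arm
#' with the printed group values as generator parameters. Per-subject
#' dispersions default to the printed +/- values (the source tables state
#' no variance model, so these are simulation choices).
#'
#' @param out_dir output directory for tables.
#' @param seed master seed; all per-subject seeds derive from it.
#' @param fast if TRUE (default) uses small grids/domains sized for test
#'   and acceptance budgets; the statistical structure is unchanged.
#' @return nested list of class `experiment_config`.
#' @export
default_experiment_config <- function(out_dir = tempfile("cohort"),
                                      seed = 1L, fast = TRUE) {
  structure(list(
    seed = seed, out_dir = out_dir,
    dsc = list(
      days = c(1, 3, 5),
      arms = list(
        saline = list(n = 11, rcbv_mean = c(0.89, 1.00, 1.13),
                      rcbv_sd = c(0.13, 0.21, 0.23)),
        dexamethasone = list(n = 13, rcbv_mean = c(1.00, 0.65, 1.26),
                             rcbv_sd = c(0.15, 0.13, 0.19))),
      noise_sd = 10, grid_dim = c(12L, 12L, 1L)),
    morphometry = list(
      arms = list(
        saline = list(n = 4, density_mean = 74.29, density_sd = 3.51,
                      angle_mean_deg = 60, seg_length_mean_mm = 0.22,
                      seg_length_min_mm = 0.15),
        dexamethasone = list(n = 5, density_mean = 41.32, density_sd = 2.34,
                             angle_mean_deg = 40, seg_length_mean_mm = 0.26,
                             seg_length_min_mm = 0.18)),
      domain_edge_mm = if (fast) 1.0 else 1.5),
    ihc = list(
      fields_per_subject = 5,
      arms = list(
        saline = list(n = 4, area_mean_um2 = 30.83, area_sd_um2 = 12),
        dexamethasone = list(n = 4, area_mean_um2 = 16.45, area_sd_um2 = 6)),
      px_um = if (fast) 1 else 0.5, n_vessels = 18),
    growth = list(
      days = c(0, 2, 4, 6, 8), cv = 0.1, y0_mm3 = 30,
      arms = list(
        saline = list(n = 11, doubling_days = 3.16),
        dexamethasone = list(n = 13, doubling_days = 2.06)))
  ), class = "experiment_config")
}

sem <- function(x) sd(x) / sqrt(length(x))

#' Run a full two-arm cohort experiment
#'
#' Simulates every modality for both arms, runs the analysis pipelines and
#' writes `rcbv.csv`, `morphometry.csv`, `tortuosity_hist.csv`, `ihc.csv`,
#' `growth.csv`, `stats.csv` and `run.log` into the config's output
#' directory. Identical config + seed reproduces byte-identical tables.
#'
#' @param config an `experiment_config` (see
#'   [default_experiment_config()]).
#' @return invisibly, a list with all tables and per-stage results.
#' @export
run_cohort <- function(config) {
  stop_if(!inherits(config, "experiment_config"),
          "'config' must be an experiment_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "run.log")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                                append = TRUE)
  cat("", file = logf)
  log_line("vasculomorph run_cohort seed=%d", config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  seeds <- child_seeds(config$seed, 4)

  ## --- DSC rCBV -----------------------------------------------------------
  rcbv_tab <- stage("dsc", {
    rows <- list()
    arm_names <- names(config$dsc$arms)
    sub_seeds <- child_seeds(seeds[1], 10000L)
    si <- 0L
    for (arm in arm_names) {
      a <- config$dsc$arms[[arm]]
      for (subj in seq_len(a$n)) {
        for (di in seq_along(config$dsc$days)) {
          si <- si + 1L
          s_ratio <- child_seeds(sub_seeds[si], 2)
          ratio <- with_seed(s_ratio[1],
                             max(0.05, rnorm(1, a$rcbv_mean[di], a$rcbv_sd[di])))
          sim <- gen_dsc(dsc_sim_spec(rcbv_ratio = ratio,
                                      noise_sd = config$dsc$noise_sd,
                                      grid_dim = config$dsc$grid_dim,
                                      seed = s_ratio[2]))
          res <- relative_cbv(integrate_cbv(compute_delta_r2star(sim$series)),
                              sim$rois)
          rows[[length(rows) + 1L]] <- data.frame(
            arm = arm, subject = sprintf("%s_%02d", arm, subj),
            day = config$dsc$days[di], tumor_mean = res$tumor_mean,
            contralateral_mean = res$contralateral_mean, rcbv = res$rcbv)
        }
      }
    }
    do.call(rbind, rows)
  })
  log_line("dsc: %d rows", nrow(rcbv_tab))

  ## --- micro-CT morphometry ----------------------------------------------
  morpho <- stage("morphometry", {
    sub_seeds <- child_seeds(seeds[2], 1000L)
    si <- 0L
    summaries <- list(); rows <- list(); tort_rows <- list()
    for (arm in names(config$morphometry$arms)) {
      a <- config$morphometry$arms[[arm]]
      arm_sum <- list()
      for (subj in seq_len(a$n)) {
        si <- si + 1L
        ss <- child_seeds(sub_seeds[si], 2)
        dens <- with_seed(ss[1], max(5, rnorm(1, a$density_mean, a$density_sd)))
        spec <- tree_spec(domain_edge_mm = config$morphometry$domain_edge_mm,
                          target_density = dens,
                          angle_mean_deg = a$angle_mean_deg,
                          seg_length_mean_mm = a$seg_length_mean_mm,
                          seg_length_min_mm = a$seg_length_min_mm %||% 0.15,
                          seed = ss[2])
        ms <- measure_tree(gen_tree(spec))
        arm_sum[[subj]] <- ms
        rows[[length(rows) + 1L]] <- data.frame(
          arm = arm, subject = sprintf("%s_%02d", arm, subj),
          target_density = dens, n_branches = ms$n_branches,
          volume_mm3 = ms$volume_mm3, density_per_mm3 = ms$density_per_mm3)
        if (length(ms$tortuosity_deg_per_mm)) {
          tort_rows[[length(tort_rows) + 1L]] <- data.frame(
            arm = arm, subject = sprintf("%s_%02d", arm, subj),
            tortuosity_deg_per_mm = ms$tortuosity_deg_per_mm)
        }
      }
      summaries[[arm]] <- arm_sum
    }
    cmp <- compare_morphometry(summaries[[1]], summaries[[2]])
    list(table = do.call(rbind, rows), tort = do.call(rbind, tort_rows),
         summaries = summaries, compare = cmp)
  })
  log_line("morphometry: %d subjects", nrow(morpho$table))

  ## --- IHC ----------------------------------------------------------------
  ihc <- stage("ihc", {
    sub_seeds <- child_seeds(seeds[3], 1000L)
    si <- 0L
    rows <- list(); groups <- list()
    for (arm in names(config$ihc$arms)) {
      a <- config$ihc$arms[[arm]]
      arm_sum <- list()
      for (subj in seq_len(a$n)) {
        for (f in seq_len(config$ihc$fields_per_subject)) {
          si <- si + 1L
          sim <- gen_ihc(ihc_sim_spec(px_um = config$ihc$px_um,
                                      n_vessels = config$ihc$n_vessels,
                                      area_mean_um2 = a$area_mean_um2,
                                      area_sd_um2 = a$area_sd_um2,
                                      seed = sub_seeds[si]))
          fs <- measure_fields(segment_vessels(sim$field), config$ihc$px_um)
          arm_sum[[length(arm_sum) + 1L]] <- fs
          rows[[length(rows) + 1L]] <- data.frame(
            arm = arm, subject = sprintf("%s_%02d", arm, subj), field = f,
            n_vessels = fs$n_vessels, mean_area_um2 = fs$mean_area_um2)
        }
      }
      groups[[arm]] <- arm_sum
    }
    cmp <- compare_vessel_area(groups[[1]], groups[[2]])
    list(table = do.call(rbind, rows), groups = groups, compare = cmp)
  })
  log_line("ihc: %d fields", nrow(ihc$table))

  ## --- growth -------------------------------------------------------------
  growth <- stage("growth", {
    sub_seeds <- child_seeds(seeds[4], 1000L)
    si <- 0L
    rows <- list(); fits <- list()
    for (arm in names(config$growth$arms)) {
      a <- config$growth$arms[[arm]]
      for (subj in seq_len(a$n)) {
        si <- si + 1L
        ser <- gen_growth(growth_sim_spec(y0_mm3 = config$growth$y0_mm3,
                                          doubling_days = a$doubling_days,
                                          cv = config$growth$cv,
                                          times_days = config$growth$days,
                                          seed = sub_seeds[si]))
        fit <- fit_exponential(ser)
        rows[[length(rows) + 1L]] <- data.frame(
          arm = arm, subject = sprintf("%s_%02d", arm, subj),
          y0 = fit$y0_mm3, k = fit$k_per_day, r2 = fit$r2,
          doubling_days = fit$doubling_days)
      }
    }
    do.call(rbind, rows)
  })
  log_line("growth: %d fits", nrow(growth))

  ## --- statistics table ---------------------------------------------------
  stats_rows <- list()
  for (arm in names(config$dsc$arms)) {
    sub <- rcbv_tab[rcbv_tab$arm == arm, ]
    grp <- split(sub$rcbv, sub$day)
    # degenerate noise-free cohorts have zero within-day variance; record
    # NA rather than aborting the report
    an <- tryCatch(one_way_anova(grp),
                   error = function(e) list(F = NA_real_, p = NA_real_))
    stats_rows[[length(stats_rows) + 1L]] <- data.frame(
      modality = "rcbv", comparison = sprintf("%s across days", arm),
      test = "one-way ANOVA", statistic = an$F, p = an$p)
    bp <- tryCatch(bonferroni_pairwise(grp), error = function(e) NULL)
    for (r in seq_len(NROW(bp))) {
      stats_rows[[length(stats_rows) + 1L]] <- data.frame(
        modality = "rcbv",
        comparison = sprintf("%s day %s vs day %s", arm, bp$group1[r],
                             bp$group2[r]),
        test = "Bonferroni post test", statistic = bp$t[r], p = bp$p[r])
    }
  }
  stats_rows[[length(stats_rows) + 1L]] <- data.frame(
    modality = "density", comparison = "saline vs dexamethasone",
    test = "unpaired t", statistic = morpho$compare$density_t,
    p = morpho$compare$density_p)
  stats_rows[[length(stats_rows) + 1L]] <- data.frame(
    modality = "tortuosity", comparison = "saline vs dexamethasone",
    test = "Mann-Whitney U", statistic = morpho$compare$tortuosity_U,
    p = morpho$compare$tortuosity_p)
  stats_rows[[length(stats_rows) + 1L]] <- data.frame(
    modality = "vessel_area", comparison = "saline vs dexamethasone",
    test = "unpaired t", statistic = ihc$compare$t, p = ihc$compare$p)
  stats_tab <- do.call(rbind, stats_rows)

  ## --- tortuosity histogram ----------------------------------------------
  tort_hist <- do.call(rbind, lapply(names(morpho$summaries), function(arm) {
    tau <- unlist(lapply(morpho$summaries[[arm]], `[[`,
                         "tortuosity_deg_per_mm"))
    breaks <- seq(0, ceiling(max(tau, 25) / 25) * 25, by = 25)
    h <- hist(tau, breaks = breaks, plot = FALSE)
    data.frame(arm = arm, lo = head(breaks, -1), hi = breaks[-1],
               count = h$counts)
  }))

  out <- function(df, name) {
    write.csv(df, file.path(config$out_dir, name), row.names = FALSE)
  }
  out(rcbv_tab, "rcbv.csv")
  out(morpho$table, "morphometry.csv")
  out(tort_hist, "tortuosity_hist.csv")
  out(ihc$table, "ihc.csv")
  out(growth, "growth.csv")
  out(stats_tab, "stats.csv")
  log_line("done")
  invisible(list(rcbv = rcbv_tab, morphometry = morpho, ihc = ihc,
                 growth = growth, stats = stats_tab,
                 tortuosity_hist = tort_hist, out_dir = config$out_dir))
}

#' Measure a generated tree with the full morphometry pipeline
#'
#' Convenience composition used throughout tests and reports: rasterized
#' volume -> skeleton -> branch graph -> whole-domain VOI summary.
#'
#' @param tree result of [gen_tree()] (list with `truth` and `volume`).
#' @param ... passed to [extract_graph()].
#' @return a `morphometry_summary`.
#' @export
measure_tree <- function(tree, ...) {
  sk <- skeletonize_3d(tree$volume)
  edge <- tree$truth$domain_edge_mm
  # the generator roots its trees at the -x face center; orienting the
  # measured graph from the same entry keeps parentage (and so angles)
  # aligned with the planted truth
  g <- extract_graph(sk, root_mm = c(0, edge / 2, edge / 2), ...)
  vessel_density(g, voi("box", center_mm = rep(edge / 2, 3), size_mm = edge))
}
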