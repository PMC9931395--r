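# Pipeline orchestration: configuration, per-subject processing of all five
# myelin-sensitive channels, cohort calibration, VOI statistics, and the
# end-to-end runner with NIfTI/CSV/JSON outputs and provenance sidecars.

#' Pipeline configuration
#'
#' Bundles every tunable default of the processing chain. All entries are
#' serialized into the provenance sidecar of each output.
#'
#' @param t2_min,t2_max,n_t2,window_max T2 grid (ms), see [t2_grid()].
#' @param reg_factor NNLS misfit inflation factor.
#' @param flip_correction per-voxel flip-angle estimation on/off.
#' @param refocusing_flip nominal refocusing flip in degrees (used by the
#'   simulator and as the SPIJN dictionary angle).
#' @param sparsity_weight,max_components SPIJN settings.
#' @param ihmtr_dialect `"dual-m0"` or `"single-m0"`.
#' @param pd_mode `"csf100"` or `"wm69"`.
#' @param kappa_my,kappa_nm hydration model constants.
#' @param g_target splenium calibration target.
#' @param seed master seed.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(t2_min = 10, t2_max = 2000, n_t2 = 40,
                            window_max = 40, reg_factor = 1.02,
                            flip_correction = TRUE, refocusing_flip = 165,
                            sparsity_weight = 0.02, max_components = 6,
                            ihmtr_dialect = "dual-m0", pd_mode = "csf100",
                            kappa_my = 0.36, kappa_nm = 0.86,
                            g_target = 0.7, seed = 1) {
  cfg <- list(t2_min = t2_min, t2_max = t2_max, n_t2 = n_t2,
              window_max = window_max, reg_factor = reg_factor,
              flip_correction = flip_correction,
              refocusing_flip = refocusing_flip,
              sparsity_weight = sparsity_weight,
              max_components = max_components,
              ihmtr_dialect = match.arg(ihmtr_dialect,
                                        c("dual-m0", "single-m0")),
              pd_mode = match.arg(pd_mode, c("csf100", "wm69")),
              kappa_my = kappa_my, kappa_nm = kappa_nm,
              g_target = g_target, seed = as.integer(seed))
  stopifnot(cfg$reg_factor >= 1, cfg$n_t2 >= 2,
            cfg$g_target > 0, cfg$g_target < 1)
  hydration_model(cfg$kappa_my, cfg$kappa_nm) # validates the kappas
  t2_grid(cfg$t2_min, cfg$t2_max, cfg$n_t2, cfg$window_max)
  structure(cfg, class = "pipeline_config")
}

#' Simulate a full cohort
#'
#' @param spec a [cohort_spec].
#' @param channels acquisitions to simulate per subject.
#' @param refocusing_flip refocusing flip for the echo series.
#' @return list of `phantom_subject`s (healthy first), named by subject id.
#' @export
simulate_cohort <- function(spec,
                            channels = c("echo", "mt", "mtsat", "noddi"),
                            refocusing_flip = 165) {
  seeds <- cohort_seeds(spec)
  kinds <- rep(c("healthy", "patient"),
               c(spec$n_healthy, spec$n_patients))
  subjects <- Map(function(kind, sd, id)
    simulate_subject(spec, kind, sd, id = id, channels = channels,
                     refocusing_flip = refocusing_flip),
    kinds, seeds, names(seeds))
  names(subjects) <- names(seeds)
  subjects
}

#' Process one subject into the five myelin-sensitive maps
#'
#' Runs MWF fitting (both algorithms) on the echo series, ihMTR on the MT
#' quadruple, and MTsat/R1/PD/MTV on the gradient-echo triple, whichever
#' inputs are present; missing inputs skip their channels.
#'
#' @param subject a `phantom_subject` (or any list with `echo`, `mt_quad`,
#'   `mtsat_in`, `noddi`, `vois` entries).
#' @param config a [pipeline_config].
#' @param mwf_mask optional fitting mask (default: the series mask).
#' @return named list of [volume_map]s (subset of `mwf_nnls`, `mwf_spijn`,
#'   `ihmtr`, `mtsat`, `r1`, `a_app`, `pd`, `mtv`) plus `skipped`.
#' @export
process_subject <- function(subject, config = pipeline_config(),
                            mwf_mask = NULL) {
  out <- list()
  skipped <- character(0)
  grid <- t2_grid(config$t2_min, config$t2_max, config$n_t2,
                  config$window_max)
  if (!is.null(subject$echo)) {
    series <- subject$echo
    if (!is.null(mwf_mask)) {
      series$mask <- as_mask(mwf_mask)
    }
    params <- epg_params(config$refocusing_flip, 1000, series$echo_spacing,
                         length(series$echo_times))
    out$mwf_nnls <- fit_mwf_nnls(series, grid, params,
                                 reg_factor = config$reg_factor,
                                 flip_correction = config$flip_correction)
    out$mwf_spijn <- fit_mwf_spijn(series, grid, params,
                                   sparsity_weight = config$sparsity_weight,
                                   max_components = config$max_components)
  } else skipped <- c(skipped, "mwf_nnls", "mwf_spijn")
  if (!is.null(subject$mt_quad)) {
    out$ihmtr <- compute_ihmtr(subject$mt_quad,
                               dialect = config$ihmtr_dialect)
  } else skipped <- c(skipped, "ihmtr")
  if (!is.null(subject$mtsat_in)) {
    fit <- fit_mtsat(subject$mtsat_in)
    out$mtsat <- fit$mtsat
    out$r1 <- fit$r1
    out$a_app <- fit$a_app
    out$pd <- calibrate_pd(fit$a_app, pd_calibration(config$pd_mode),
                           subject$vois)
    out$mtv <- compute_mtv(out$pd)
  } else skipped <- c(skipped, "mtsat", "mtv")
  out$skipped <- skipped
  out
}

gratio_methods <- function() c("mwf_nnls", "mwf_spijn", "ihmtr", "mtsat",
                               "mtv")

#' Run the whole pipeline on a synthetic cohort
#'
#' Simulate (per `spec`) -> fit both MWF maps -> MT maps -> calibrate the
#' linear scalings on the healthy splenium -> five g-ratio map sets per
#' subject -> VOI statistics. When `out_dir` is given, writes per-subject
#' NIfTI volumes, the three tidy CSV tables (`voi_means.csv`, `ttests.csv`,
#' `correlations.csv`) and a provenance JSON.
#'
#' @param spec a [cohort_spec].
#' @param config a [pipeline_config].
#' @param out_dir optional output directory.
#' @param channels acquisitions to simulate (dropping `"echo"` skips the
#'   expensive MWF channels).
#' @param mwf_voi restrict MWF fitting to these VOI roles (default
#'   `c("WM", "GM", "CSF", "lesion", "perilesion")`; `NULL` fits the whole
#'   brain mask).
#' @return A `pipeline_result` list: `subjects`, `maps`, `gratio`,
#'   `alphas`, `report`, `config`.
#' @export
run_all <- function(spec, config = pipeline_config(), out_dir = NULL,
                    channels = c("echo", "mt", "mtsat", "noddi"),
                    mwf_voi = c("WM", "GM", "CSF", "lesion",
                                "perilesion")) {
  subjects <- simulate_cohort(spec, channels = channels,
                              refocusing_flip = config$refocusing_flip)
  maps <- lapply(subjects, function(su) {
    mask <- NULL
    if (!is.null(mwf_voi) && !is.null(su$echo)) {
      mask <- Reduce(`|`, lapply(mwf_voi, function(r) as_mask(su$vois[[r]])))
    }
    process_subject(su, config, mwf_mask = mask)
  })
  healthy <- names(subjects)[vapply(subjects, function(s)
    s$group == "healthy", TRUE)]
  model <- hydration_model(config$kappa_my, config$kappa_nm)
  # splenium calibration of the two linear MT channels on healthy subjects
  alphas <- list()
  for (mt in c("ihmtr", "mtsat")) {
    if (all(vapply(maps[healthy], function(m) !is.null(m[[mt]]), TRUE))) {
      alphas[[mt]] <- calibrate_alpha(
        lapply(maps[healthy], `[[`, mt),
        lapply(subjects[healthy], `[[`, "noddi"),
        lapply(subjects[healthy], function(s) s$vois$splenium),
        g_target = config$g_target)
    }
  }
  methods <- intersect(gratio_methods(),
                       unique(unlist(lapply(maps, names))))
  gratio <- lapply(names(subjects), function(id) {
    m <- maps[[id]]
    res <- list()
    for (me in methods) {
      if (is.null(m[[me]])) next
      res[[me]] <- run_gratio_pipeline(m, subjects[[id]]$noddi, method = me,
                                       alpha = alphas[[me]], model = model)
    }
    res
  })
  names(gratio) <- names(subjects)

  tables <- lapply(names(subjects), function(id) {
    mm <- maps[[id]][intersect(names(maps[[id]]), gratio_methods())]
    for (me in names(gratio[[id]]))
      mm[[paste0("g_", me)]] <- gratio[[id]][[me]]$g
    extract_voi_means(mm, subjects[[id]]$vois, per_lesion = FALSE)
  })
  names(tables) <- names(subjects)
  report <- build_cohort_report(tables, vapply(subjects, `[[`, "",
                                               "group"))
  result <- structure(list(subjects = subjects, maps = maps,
                           gratio = gratio, alphas = alphas,
                           report = report, config = config),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

#' Write pipeline outputs to a directory
#'
#' @param result a `pipeline_result`.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(result$maps)) {
    sdir <- file.path(out_dir, id)
    dir.create(sdir, showWarnings = FALSE)
    roles <- list()
    for (nm in setdiff(names(result$maps[[id]]), "skipped")) {
      f <- file.path(sdir, paste0(nm, ".nii"))
      write_volume(result$maps[[id]][[nm]], f)
      roles[[nm]] <- basename(f)
    }
    for (me in names(result$gratio[[id]])) {
      f <- file.path(sdir, paste0("g_", me, ".nii"))
      write_volume(result$gratio[[id]][[me]]$g, f)
      roles[[paste0("g_", me)]] <- basename(f)
    }
    jsonlite::write_json(list(subject = id,
                              group = result$subjects[[id]]$group,
                              roles = roles),
                         file.path(sdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  rep <- result$report
  write.csv(rep$voi_means, file.path(out_dir, "voi_means.csv"),
            row.names = FALSE)
  if (!is.null(rep$ttests))
    write.csv(rep$ttests, file.path(out_dir, "ttests.csv"),
              row.names = FALSE)
  if (!is.null(rep$correlations))
    write.csv(rep$correlations, file.path(out_dir, "correlations.csv"),
              row.names = FALSE)
  cfg <- unclass(result$config)
  jsonlite::write_json(list(config = cfg, alphas = result$alphas,
                            config_hash = digest_config(cfg),
                            n_tests = rep$n_tests),
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

# stable hash of the configuration (provenance sidecars)
digest_config <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(x)
    paste(format(x, digits = 15), collapse = ","), ""), collapse = ";",
    sep = "=")
  # simple polynomial rolling hash, enough for provenance fingerprinting
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
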