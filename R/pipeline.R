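# End-to-end orchestration: phantom (or files) -> preprocessing ->
# registration -> Jacobian/strain -> aeration at both phases -> pull-back ->
# joint structure / PRM -> recruitment and vertical ROIs -> report.

#' Case configuration
#'
#' Exactly one input source: either a [phantom_spec()] or a list of file
#' paths (`ee`, `ei`, `mask_ee`, `mask_ei`, NIfTI).
#'
#' @param phantom A [phantom_spec()], or NULL when reading files.
#' @param paths Named list of NIfTI paths, or NULL when using a phantom.
#' @param registration A [registration_config()].
#' @param out_dir Output directory for intermediates and the report; NULL
#'   keeps everything in memory.
#' @param subject Subject identifier recorded in the report.
#' @param condition Condition/strategy label recorded in the report.
#' @param n_rois Number of vertical ROIs.
#' @param run_registration Set FALSE to skip registration (aeration and
#'   recruitment metrics only).
#' @param seed Seed recorded in the report (phantom determinism lives in the
#'   phantom spec; this seed is applied before any stage that draws random
#'   numbers).
#' @return A list of class `case_config`.
#' @export
case_config <- function(phantom = NULL, paths = NULL,
                        registration = registration_config(),
                        out_dir = NULL, subject = "subject1",
                        condition = "condition1", n_rois = 10L,
                        run_registration = TRUE, seed = 1L) {
  if (is.null(phantom) == is.null(paths))
    stop("exactly one input source: phantom spec XOR file paths")
  if (!is.null(paths))
    stopifnot(all(c("ee", "ei", "mask_ee", "mask_ei") %in% names(paths)))
  structure(list(phantom = phantom, paths = paths,
                 registration = registration, out_dir = out_dir,
                 subject = subject, condition = condition,
                 n_rois = as.integer(n_rois),
                 run_registration = isTRUE(run_registration),
                 seed = as.integer(seed)),
            class = "case_config")
}

.write_case_outputs <- function(out_dir, vols, tables, report) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(vols))
    write_volume(vols[[nm]], file.path(out_dir, paste0(nm, ".nii.gz")))
  for (nm in names(tables))
    utils::write.csv(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(out_dir)
}

#' Run one case end to end
#'
#' Executes phantom generation (or file loading), registration, Jacobian
#' and strain, aeration analysis of both phases, pull-back of
#' end-inspiratory aeration, strain-aeration joint structure and parametric
#' response map, tidal recruitment and vertical ROI profiles, and collects
#' every scalar metric in a report. When the case is a phantom, a
#' truth-recovery block (strain error, recruitment error, mass-conservation
#' mismatch) is included. Intermediates are written when `out_dir` is set.
#'
#' @param cfg A [case_config()].
#' @return A list of class `case_report` (also written as JSON when
#'   `out_dir` is set) with elements `meta`, `aeration`, `strain`,
#'   `recruitment`, `rois`, `registration`, `truth_recovery` and the
#'   in-memory objects in `objects`.
#' @export
run_case <- function(cfg) {
  stopifnot(inherits(cfg, "case_config"))
  set.seed(cfg$seed)
  truth <- NULL
  if (!is.null(cfg$phantom)) {
    ph <- generate_phantom(cfg$phantom)
    ee <- ph$ee$ct; mask_ee <- ph$ee$mask
    ei <- ph$ei$ct; mask_ei <- ph$ei$mask
    truth <- ph$truth
  } else {
    ee <- read_volume(cfg$paths$ee, "ct")
    ei <- read_volume(cfg$paths$ei, "ct")
    mask_ee <- read_volume(cfg$paths$mask_ee, "mask")
    mask_ei <- read_volume(cfg$paths$mask_ei, "mask")
  }
  fgas_ee <- hu_to_fgas(ee, mask_ee)
  fgas_ei <- hu_to_fgas(ei, mask_ei)
  ms_ee <- mass_summary(fgas_ee)
  ms_ei <- mass_summary(fgas_ei)

  aer <- list(
    ee = list(mean = mean(fgas_ee$data, na.rm = TRUE),
              p95 = percentile95(fgas_ee),
              cov = heterogeneity(fgas_ee, mask_ee)$cov,
              mass_percent = as.list(ms_ee$percent),
              total_mass_g = ms_ee$total_mass_g,
              eelv_ml = ms_ee$gas_volume_ml),
    ei = list(mean = mean(fgas_ei$data, na.rm = TRUE),
              p95 = percentile95(fgas_ei),
              cov = heterogeneity(fgas_ei, mask_ei)$cov,
              mass_percent = as.list(ms_ei$percent),
              total_mass_g = ms_ei$total_mass_g,
              gas_volume_ml = ms_ei$gas_volume_ml),
    delta = delta_aeration(mean(fgas_ei$data, na.rm = TRUE),
                           mean(fgas_ee$data, na.rm = TRUE)))

  tr <- tidal_recruitment(ms_ee, ms_ei)
  part_ee <- vertical_rois(mask_ee, cfg$n_rois)
  regional <- regional_recruitment(fgas_ee, fgas_ei, mask_ee, mask_ei,
                                   cfg$n_rois)
  intratidal <- intratidal_change(ms_ee, ms_ei)

  objects <- list(fgas_ee = fgas_ee, fgas_ei = fgas_ei)
  vols <- list(fgas_ee = fgas_ee, fgas_ei = fgas_ei)
  strain_block <- NULL; reg_block <- NULL
  joint <- NULL; prm_map <- NULL
  profile <- NULL

  if (cfg$run_registration) {
    reg <- register_pair(ee, ei, mask_ei, cfg$registration,
                         mask_ee = mask_ee)
    jm <- jacobian_map(reg$field, mask_ee)
    strain <- jm$strain
    fgas_ei_on_ee <- ei_aeration_on_ee_grid(fgas_ei, reg$field, mask_ee)
    ss <- strain_summary(strain)
    strain_block <- list(mean = ss$mean, p95 = ss$p95, cov = ss$cov,
                         cov_filtered = heterogeneity(strain, mask_ee)$cov,
                         median = regional_strain(strain, mask_ee))
    reg_block <- list(metric = reg$metric, jmin = reg$jmin, jmax = reg$jmax,
                      stages = reg$stages)
    joint <- strain_vs_aeration(strain, fgas_ei_on_ee, mask_ee)
    prm_map <- prm(fgas_ee, fgas_ei_on_ee, strain, mask_ee)
    profile <- roi_profile(part_ee, fgas_ee, strain)
    objects <- c(objects,
                 list(field = reg$field, strain = strain,
                      jacobian = jm$jacobian, fgas_ei_on_ee = fgas_ei_on_ee,
                      joint = joint, prm = prm_map))
    vols <- c(vols, list(field = reg$field, strain = strain))
  } else {
    profile <- roi_profile(part_ee, fgas_ee)
  }

  truth_recovery <- NULL
  if (!is.null(truth)) {
    mass_mismatch <- abs(ms_ei$total_mass_g - ms_ee$total_mass_g) /
      ms_ee$total_mass_g
    truth_recovery <- list(
      recruited_fraction_true = truth$recruited_fraction,
      tidal_recruitment_error = tr - truth$recruited_fraction,
      mass_conservation_mismatch = mass_mismatch)
    if (cfg$run_registration) {
      m <- objects$strain$data
      sel <- !is.na(m) & !is.na(truth$strain$data)
      err <- m[sel] - truth$strain$data[sel]
      du <- objects$field$data - truth$field$data
      epe <- sqrt(du[, , , 1]^2 + du[, , , 2]^2 + du[, , , 3]^2)
      truth_recovery$strain_mae <- mean(abs(err))
      truth_recovery$strain_median_abs_error <- stats::median(abs(err))
      truth_recovery$mean_strain_error <-
        mean(m[sel]) - mean(truth$strain$data[sel])
      truth_recovery$median_epe_mm <- stats::median(epe[sel])
    }
  }

  report <- list(
    meta = list(package_version =
                  as.character(utils::packageVersion("lungstrain")),
                subject = cfg$subject, condition = cfg$condition,
                seed = cfg$seed, n_rois = cfg$n_rois,
                input = if (is.null(cfg$phantom)) "files" else "phantom",
                config_hash = .config_hash(cfg)),
    aeration = aer,
    strain = strain_block,
    recruitment = list(tidal_recruitment = tr,
                       regional = regional,
                       intratidal = intratidal),
    rois = profile,
    registration = reg_block,
    truth_recovery = truth_recovery)
  if (!is.null(cfg$out_dir)) {
    tables <- list(regional_recruitment = regional,
                   intratidal_change = intratidal, roi_profile = profile)
    if (!is.null(joint)) tables$strain_aeration <- joint$intervals
    if (!is.null(prm_map)) {
      tables$prm_volume_fraction <- as.data.frame(prm_map$volume_fraction)
      tables$prm_mean_strain <- as.data.frame(prm_map$mean_strain)
    }
    .write_case_outputs(cfg$out_dir, vols,
                        tables,
                        report[setdiff(names(report), "objects")])
  }
  report$objects <- objects
  class(report) <- "case_report"
  report
}

# Deterministic hash of the configuration (seed + parameters).
.config_hash <- function(cfg) {
  s <- utils::capture.output(utils::str(
    cfg[setdiff(names(cfg), "out_dir")], digits.d = 12))
  sum(utils::head(cumsum(as.integer(charToRaw(paste(s, collapse = "\n")))),
                  1e6)) %% 2147483647
}

#' Compare two ventilation strategies across matched subjects
#'
#' Paired comparisons of the scalar metrics of two report sets (same
#' subjects, two strategies): paired t-tests, the delta-aeration versus
#' mean-strain correlation, and a region x strategy repeated-measures ANOVA
#' of the ROI mean-aeration (and mean-strain) profiles.
#'
#' @param reports_a,reports_b Lists of [run_case()] reports, matched by
#'   position (same subjects, strategies A and B).
#' @return A list with `paired` (data frame: metric, mean_a, mean_b, t, df,
#'   p), `correlation` (delta aeration vs mean strain across all cases),
#'   `roi_anova_aeration` and (when strain is present) `roi_anova_strain`.
#' @export
compare_strategies <- function(reports_a, reports_b) {
  if (length(reports_a) != length(reports_b))
    stop("unmatched subject sets")
  n <- length(reports_a)
  if (n < 2L) stop("need at least two matched subjects")
  subj_a <- vapply(reports_a, function(r) r$meta$subject, character(1))
  subj_b <- vapply(reports_b, function(r) r$meta$subject, character(1))
  if (!identical(subj_a, subj_b)) stop("unmatched subject sets")
  scalar <- function(r) {
    out <- c(mean_fgas_ee = r$aeration$ee$mean,
             p95_fgas_ee = r$aeration$ee$p95,
             cov_fgas_ee = r$aeration$ee$cov,
             mean_fgas_ei = r$aeration$ei$mean,
             p95_fgas_ei = r$aeration$ei$p95,
             cov_fgas_ei = r$aeration$ei$cov,
             eelv_ml = r$aeration$ee$eelv_ml,
             delta_aeration = r$aeration$delta,
             tidal_recruitment = r$recruitment$tidal_recruitment)
    if (!is.null(r$strain))
      out <- c(out, mean_strain = r$strain$mean, p95_strain = r$strain$p95,
               cov_strain = r$strain$cov)
    out
  }
  ma <- t(vapply(reports_a, scalar, scalar(reports_a[[1]])))
  mb <- t(vapply(reports_b, scalar, scalar(reports_b[[1]])))
  paired <- do.call(rbind, lapply(colnames(ma), function(m) {
    res <- tryCatch(paired_t(ma[, m], mb[, m]), error = function(e) NULL)
    data.frame(metric = m, mean_a = mean(ma[, m]), mean_b = mean(mb[, m]),
               t = if (is.null(res)) NA_real_ else res$t,
               df = if (is.null(res)) NA_real_ else res$df,
               p = if (is.null(res)) NA_real_ else res$p)
  }))
  out <- list(paired = paired)
  if ("mean_strain" %in% colnames(ma)) {
    out$correlation <- correlation_test(
      c(ma[, "delta_aeration"], mb[, "delta_aeration"]),
      c(ma[, "mean_strain"], mb[, "mean_strain"]))
  }
  roi_design <- function(col) {
    grab <- function(reports, strat)
      do.call(rbind, lapply(seq_along(reports), function(i) {
        pr <- reports[[i]]$rois
        data.frame(value = pr[[col]], subject = subj_a[i],
                   region = pr$roi, strategy = strat)
      }))
    rbind(grab(reports_a, "A"), grab(reports_b, "B"))
  }
  out$roi_anova_aeration <- rm_anova_two_way(roi_design("mean_fgas"))
  if (!is.null(reports_a[[1]]$rois$mean_strain))
    out$roi_anova_strain <- rm_anova_two_way(roi_design("mean_strain"))
  out
}
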