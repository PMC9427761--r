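#' Default pipeline run configuration
#'
#' Nested stage configuration for \code{\link{run_pipeline}}: cohort
#' generation, ring geometry, feature extraction, signature fitting and
#' evaluation. All method parameters (2 mm / 1 mm ring band, HU exclusion
#' thresholds, six texture bin counts, mRMR k = 30, 5 CV folds, tertile
#' grouping) surface here rather than being hard-coded. A YAML file with
#' the same structure can override any subset of fields.
#'
#' @param seed global seed; per-stage seeds are derived from it by fixed
#'   offsets.
#' @return nested list of class \code{run_config}.
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    cohort = list(n_cases = 60, grid_shape = c(48, 48, 48),
                  spacing_mm = c(1, 1, 1)),
    geometry = list(outer_mm = 2, inner_mm = 1,
                    air_hu = -500, vessel_hu = 300),
    features = list(bin_counts = c(8, 16, 32, 64, 128, 256)),
    signature = list(k = 30, nfolds = 5),
    evaluation = list(n_boot = 200)),
    class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Fields present in the file override the defaults; everything else keeps
#' its default value.
#'
#' @param path YAML file path.
#' @inheritParams default_run_config
#' @export
read_run_config <- function(path, seed = 1L) {
  user <- yaml::read_yaml(path)
  cfg <- default_run_config(seed)
  for (blk in names(user)) {
    if (blk == "seed") { cfg$seed <- as.integer(user$seed); next }
    if (!blk %in% names(cfg))
      ring_stop(paste0("unknown config block: ", blk), "validation_error")
    for (fld in names(user[[blk]])) cfg[[blk]][[fld]] <- user[[blk]][[fld]]
  }
  cfg
}

#' Run the full pipeline: simulate, ring, extract, fit, evaluate
#'
#' Generates a synthetic cohort, extracts the paired-region feature table,
#' fits the radiomics signature on NLR-High vs NLR-Low training labels,
#' scores every case, and evaluates: ROC (High vs Low and High vs rest),
#' Kaplan-Meier/log-rank by NLR status and RS group, univariate and
#' multivariate Cox models for DFS and OS with C-indices, and (when the
#' cohort has an immunotherapy subset) the response-rate table. Stage CSVs,
#' the serialized signature and a manifest with config hash, seed and
#' output checksums land in \code{out_dir}; a rerun with the same config
#' and seed reproduces identical checksums.
#'
#' @param config a \code{run_config}; missing blocks raise a validation
#'   error.
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly; its \code{results} element carries the
#'   in-memory stage outputs.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = tempfile()) {
  for (blk in c("cohort", "geometry", "features", "signature", "evaluation"))
    if (is.null(config[[blk]]))
      ring_stop(paste0("config is missing the '", blk, "' block"),
                "validation_error")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)

  ccfg <- do.call(cohort_config,
                  c(config$cohort, list(seed = seed + 1000L)))
  cohort <- generate_cohort(ccfg)
  clinical <- cohort$clinical

  geom <- config$geometry
  feats <- extract_cohort(cohort$cases,
                          outer_mm = geom$outer_mm, inner_mm = geom$inner_mm,
                          air_hu = geom$air_hu, vessel_hu = geom$vessel_hu,
                          bin_counts = config$features$bin_counts)
  write.csv(feats, file.path(out_dir, "features.csv"), row.names = FALSE)
  write.csv(clinical, file.path(out_dir, "clinical.csv"), row.names = FALSE)

  hl <- clinical$nlr_status %in% c("High", "Low")
  xm <- as.matrix(feats[, -1])
  rownames(xm) <- feats$case_id
  sig <- rs_fit(xm[hl, , drop = FALSE],
                as.integer(clinical$nlr_status[hl] == "High"),
                k = config$signature$k, nfolds = config$signature$nfolds,
                seed = seed + 2000L)
  write_signature(sig, file.path(out_dir, "signature.json"))

  rs <- compute_rs(sig, xm)
  rs_group <- assign_rs_group(rs, sig$tertile_cutoffs)

  roc_hl <- roc_auc(rs[hl], as.integer(clinical$nlr_status[hl] == "High"))
  roc_hml <- roc_auc(rs, as.integer(clinical$nlr_status == "High"))
  roc_tab <- data.frame(contrast = c("High_vs_Low", "High_vs_MixLow"),
                        auc = c(roc_hl$auc, roc_hml$auc),
                        ci_low = c(roc_hl$ci_low, roc_hml$ci_low),
                        ci_high = c(roc_hl$ci_high, roc_hml$ci_high))
  write.csv(roc_tab, file.path(out_dir, "roc.csv"), row.names = FALSE)

  km_rows <- list()
  for (grp_var in c("nlr_status", "rs_group")) {
    gv <- if (grp_var == "rs_group") rs_group else clinical[[grp_var]]
    for (g in sort(unique(gv))) {
      ii <- gv == g
      for (oc in c("dfs", "os")) {
        cv <- km_estimate(clinical[[paste0(oc, "_time")]][ii],
                          clinical[[paste0(oc, "_event")]][ii])
        if (nrow(cv) > 0)
          km_rows[[length(km_rows) + 1]] <-
            cbind(data.frame(grouping = grp_var, group = g, outcome = oc),
                  as.data.frame(cv))
      }
    }
  }
  km_tab <- do.call(rbind, km_rows)
  write.csv(km_tab, file.path(out_dir, "km_curves.csv"), row.names = FALSE)
  logrank <- list(
    dfs_by_status = logrank_test(clinical$dfs_time, clinical$dfs_event,
                                 clinical$nlr_status),
    dfs_by_rs = logrank_test(clinical$dfs_time, clinical$dfs_event,
                             rs_group),
    os_by_rs = logrank_test(clinical$os_time, clinical$os_event, rs_group))

  cdat <- cbind(clinical, rs = rs)
  covs <- c("rs", "age", "sex", "t_stage", "n_stage", "m_stage")
  cox <- list(dfs = cox_fit(cdat, "dfs_time", "dfs_event", covs),
              os = cox_fit(cdat, "os_time", "os_event", covs))
  for (oc in names(cox)) {
    write.csv(cox[[oc]]$univariate,
              file.path(out_dir, paste0("cox_univariate_", oc, ".csv")),
              row.names = FALSE)
    write.csv(cox[[oc]]$multivariate,
              file.path(out_dir, paste0("cox_multivariate_", oc, ".csv")),
              row.names = FALSE)
  }

  resp <- NULL
  has_resp <- !is.na(clinical$response)
  if (sum(has_resp) >= 6 &&
      length(unique(clinical$response[has_resp])) >= 2) {
    resp <- response_table(clinical$response[has_resp],
                           rs_group[has_resp], rs[has_resp])
    write.csv(resp$rates, file.path(out_dir, "response_rates.csv"),
              row.names = FALSE)
  }

  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  outputs <- sort(setdiff(list.files(out_dir),
                          c("manifest.json")))
  checksums <- tools::md5sum(file.path(out_dir, outputs))
  names(checksums) <- outputs
  manifest <- list(
    package_version = as.character(utils::packageVersion("ringomics")),
    seed = seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    n_cases = nrow(clinical),
    checksums = as.list(checksums))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest$results <- list(signature = sig, rs = rs, rs_group = rs_group,
                           roc = roc_tab, logrank = logrank, cox = cox,
                           response = resp, clinical = clinical,
                           features = feats)
  invisible(manifest)
}

#' Serialize and restore a radiomics signature as JSON
#'
#' @param signature a \code{radiomics_signature}.
#' @param path JSON file path.
#' @export
write_signature <- function(signature, path) {
  payload <- list(selected = signature$selected,
                  coefficients = as.list(signature$coefficients),
                  intercept = signature$intercept,
                  standardization = signature$standardization,
                  lambda = signature$lambda,
                  tertile_cutoffs = signature$tertile_cutoffs,
                  group_labels = signature$group_labels)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(selected = p$selected,
                 coefficients = unlist(p$coefficients),
                 intercept = p$intercept,
                 standardization = p$standardization,
                 lambda = p$lambda,
                 tertile_cutoffs = p$tertile_cutoffs,
                 group_labels = p$group_labels,
                 cv_curve = NULL,
                 training = list(n = NA, nfolds = NA, rs = numeric(0))),
            class = "radiomics_signature")
}

#' Validate pipeline inputs
#'
#' Checks a cohort (volumes/masks plus clinical table) for the problems the
#' pipeline assumes away: grid misalignment, non-binary masks, missing
#' clinical columns, negative times, non-binary events and NLR labels
#' inconsistent with the stored ratios. Reporting only: returns a
#' machine-readable problem list and never throws.
#'
#' @param cases list of cases (elements with \code{case_id}, \code{volume},
#'   \code{tumor_mask}).
#' @param clinical clinical data.frame.
#' @return data.frame with columns \code{case_id}, \code{field},
#'   \code{problem}; zero rows when clean.
#' @export
validate_inputs <- function(cases, clinical) {
  probs <- list()
  note <- function(id, field, msg)
    probs[[length(probs) + 1]] <<- data.frame(case_id = id, field = field,
                                              problem = msg)
  need <- c("case_id", "nlr_intra", "nlr_peri", "nlr_status", "dfs_time",
            "dfs_event", "os_time", "os_event")
  for (cn in setdiff(need, colnames(clinical)))
    note(NA_character_, cn, "missing clinical column")
  for (cs in cases) {
    if (!same_grid(cs$volume, cs$tumor_mask))
      note(cs$case_id, "tumor_mask", "mask grid does not match volume")
    if (!is.logical(cs$tumor_mask$voxels))
      note(cs$case_id, "tumor_mask", "mask is not binary")
    else if (!any(cs$tumor_mask$voxels))
      note(cs$case_id, "tumor_mask", "mask is empty")
  }
  if (all(c("dfs_time", "os_time") %in% colnames(clinical)))
    for (tcol in c("dfs_time", "os_time", "pfs_time"))
      if (tcol %in% colnames(clinical)) {
        bad <- which(!is.na(clinical[[tcol]]) & clinical[[tcol]] < 0)
        for (i in bad) note(clinical$case_id[i], tcol, "negative time")
      }
  for (ecol in c("dfs_event", "os_event", "pfs_event"))
    if (ecol %in% colnames(clinical)) {
      bad <- which(!is.na(clinical[[ecol]]) &
                     !clinical[[ecol]] %in% c(0, 1))
      for (i in bad) note(clinical$case_id[i], ecol, "event not 0/1")
    }
  if (all(c("nlr_intra", "nlr_peri", "nlr_status") %in% colnames(clinical))) {
    lab <- nlr_status(clinical$nlr_intra, clinical$nlr_peri)
    bad <- which(lab != clinical$nlr_status)
    for (i in bad)
      note(clinical$case_id[i], "nlr_status",
           "label inconsistent with stored NLR ratios")
  }
  if (length(probs) == 0)
    return(data.frame(case_id = character(0), field = character(0),
                      problem = character(0)))
  do.call(rbind, probs)
}
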