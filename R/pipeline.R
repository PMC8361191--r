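#' Run the full coupling/heritability pipeline from a config
#'
#' Orchestrates an end-to-end run: (optionally) simulate a study, compute
#' regional coupling phenotypes, reliability statistics, regional
#' covariate models, regional heritability and network-level statistics.
#' Every intermediate table is written under a run directory named by the
#' configuration hash and seed, together with a log and a machine-
#' readable `summary.json`. Re-running with an identical config and seed
#' reproduces all outputs.
#'
#' The config is a YAML file (or an equivalent R list) with keys:
#' \describe{
#'   \item{seed}{Integer master seed.}
#'   \item{simulate}{Optional block: `n_regions`, `n_mz_pairs`,
#'     `n_dz_pairs`, `n_full_sibs`, `n_singletons`, `sigma2_A/C/E/M`,
#'     `target_coupling`, `sc_density`, `n_fc`. When present the study is
#'     generated under the run directory.}
#'   \item{paths}{For user data: `parcellation`, `connectome_dir`,
#'     `cohort`, `pedigree`. Connectome files follow the
#'     `{subject}_{modality}_{measurement}.txt` pattern.}
#'   \item{stages}{Logical toggles `couple`, `reliability`, `glm`,
#'     `heritability`, `netstats` (all default on).}
#'   \item{variant}{Coupling variant: `whole_brain` (default), `within`,
#'     `between`, `partial_distance`, `intra_hemisphere`.}
#'   \item{alpha}{FDR level (default 0.05).}
#'   \item{n_perm}{Permutations for network statistics (default 1000).}
#'   \item{subgroup_filter}{Optional R expression on cohort columns
#'     (e.g. `"age < 30"`); heritability is additionally rerun on the
#'     matching subjects.}
#' }
#'
#' @param config Path to a YAML config file, or a config list.
#' @param out_dir Base output directory.
#' @return Invisibly, the run directory path.
#' @export
run_pipeline <- function(config, out_dir = "scfc_run") {
  if (is_string(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  alpha <- config$alpha %||% 0.05
  n_perm <- as.integer(config$n_perm %||% 1000L)
  variant <- config$variant %||% "whole_brain"
  stages <- config$stages %||% list()
  on_stage <- function(s) isTRUE(stages[[s]] %||% TRUE)

  hash <- config_hash(config)
  run_dir <- file.path(out_dir, sprintf("run-%s-seed%d", hash, seed))
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(run_dir, "run.log")
  log_line <- function(...) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), sprintf(...), "\n",
        sep = "", file = log_path, append = TRUE)
  }
  log_line("scfc %s | config hash %s | seed %d",
           as.character(utils::packageVersion("scfc")), hash, seed)
  summary_out <- list(config_hash = hash, seed = seed,
                      package_version =
                        as.character(utils::packageVersion("scfc")))
  stage <- "setup"
  run_stage <- function(name, expr) {
    stage <<- name
    log_line("stage %s: start", name)
    value <- tryCatch(expr, error = function(e) {
      log_line("stage %s: FAILED: %s", name, conditionMessage(e))
      stop_scfc("pipeline stage '", name, "' failed: ",
                conditionMessage(e))
    })
    log_line("stage %s: done", name)
    value
  }

  # ---- inputs ---------------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    data_dir <- file.path(run_dir, "data")
    run_stage("simulate", {
      simulate_study(
        data_dir,
        parcellation = default_parcellation(sim$n_regions %||% 50L),
        composition = family_composition(
          sim$n_mz_pairs %||% 10L, sim$n_dz_pairs %||% 10L,
          sim$n_full_sibs %||% 20L, sim$n_singletons %||% 10L),
        truth = true_variances(sim$sigma2_A %||% 0.4,
                               sim$sigma2_C %||% 0.2,
                               sim$sigma2_E %||% 0.4,
                               sim$sigma2_M %||% 0.25),
        target_coupling = sim$target_coupling %||% 0.25,
        sc_density = sim$sc_density %||% 0.3,
        n_fc = sim$n_fc %||% 4L, seed = seed)
    })
    paths <- list(parcellation = file.path(data_dir, "parcellation.tsv"),
                  connectome_dir = file.path(data_dir, "connectomes"),
                  cohort = file.path(data_dir, "cohort.tsv"),
                  pedigree = file.path(data_dir, "pedigree.tsv"))
  } else {
    paths <- config$paths
    if (is.null(paths)) stop_scfc("config needs 'paths' or 'simulate'")
  }
  parcellation <- read_parcellation(paths$parcellation)
  pedigree <- read_pedigree(paths$pedigree)
  cohort <- read_cohort(paths$cohort)
  subjects <- pedigree$subject_id

  # ---- coupling phenotypes --------------------------------------------------
  couple_out <- run_stage("couple", {
    couple_fun <- switch(
      variant,
      whole_brain = function(sc, fc) regional_coupling(sc, fc),
      within = function(sc, fc) network_coupling(sc, fc, parcellation,
                                                 "within"),
      between = function(sc, fc) network_coupling(sc, fc, parcellation,
                                                  "between"),
      partial_distance = function(sc, fc)
        partial_coupling_distance(sc, fc, parcellation),
      intra_hemisphere = function(sc, fc)
        intra_hemisphere_coupling(sc, fc, parcellation),
      stop_scfc("unknown coupling variant '", variant, "'"))
    n_reg <- nrow(parcellation)
    per_meas <- list()
    avg_rows <- list()
    sc_strength <- list()
    fc_strength <- list()
    for (sid in subjects) {
      sc_path <- file.path(paths$connectome_dir,
                           sprintf("%s_SC_1.txt", sid))
      fc_paths <- Sys.glob(file.path(paths$connectome_dir,
                                     sprintf("%s_FC_*.txt", sid)))
      if (!file.exists(sc_path) || !length(fc_paths)) {
        stop_scfc("missing connectome files for subject ", sid)
      }
      sc <- read_connectome(sc_path, parcellation, "SC", sid)
      fcs <- lapply(seq_along(fc_paths), function(j) {
        read_connectome(fc_paths[j], parcellation, "FC", sid, j)
      })
      for (j in seq_along(fcs)) {
        cp <- couple_fun(sc, fcs[[j]])
        per_meas[[length(per_meas) + 1L]] <-
          c(list(subject_id = sid, measurement = j),
            as.list(stats::setNames(cp$value,
                                    paste0("r", seq_len(n_reg)))))
        fc_strength[[length(fc_strength) + 1L]] <-
          c(list(subject_id = sid, measurement = j),
            as.list(stats::setNames(node_strength(fcs[[j]]),
                                    paste0("r", seq_len(n_reg)))))
      }
      cp_avg <- couple_fun(sc, average_fc(fcs))
      avg_rows[[length(avg_rows) + 1L]] <-
        c(list(subject_id = sid, measurement = 1L),
          as.list(stats::setNames(cp_avg$value,
                                  paste0("r", seq_len(n_reg)))))
      sc_strength[[length(sc_strength) + 1L]] <-
        c(list(subject_id = sid, measurement = 1L),
          as.list(stats::setNames(node_strength(sc),
                                  paste0("r", seq_len(n_reg)))))
    }
    bind <- function(rows) {
      as_phenotype_table(do.call(rbind.data.frame,
                                 c(rows, stringsAsFactors = FALSE)))
    }
    out <- list(coupling_by_measurement = bind(per_meas),
                coupling_avg = bind(avg_rows),
                sc_strength = bind(sc_strength),
                fc_strength = bind(fc_strength))
    for (nm in names(out)) {
      write_table(out[[nm]], file.path(run_dir, paste0(nm, ".tsv")))
    }
    out
  })
  summary_out$n_subjects <- length(subjects)
  summary_out$n_regions <- nrow(parcellation)
  summary_out$variant <- variant

  group_mean <- function(tab, meas = NULL) {
    m <- phenotype_matrix_multi(tab, meas)
    colMeans(m, na.rm = TRUE)
  }

  # ---- reliability ----------------------------------------------------------
  n_meas <- max(couple_out$coupling_by_measurement$measurement)
  if (on_stage("reliability") && n_meas >= 2L) {
    rel <- run_stage("reliability", {
      a <- group_mean(couple_out$coupling_by_measurement, 1L)
      b <- group_mean(couple_out$coupling_by_measurement, 2L)
      ba <- bland_altman(a, b)
      agr <- agreement_correlation(a, b, n_perm = n_perm, seed = seed + 7L)
      out <- list(bias = ba$bias, sd_diff = ba$sd_diff,
                  loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
                  n = ba$n, r = agr$r, p = agr$p)
      jsonlite::write_json(out, file.path(run_dir, "reliability.json"),
                           auto_unbox = TRUE, digits = NA)
      out
    })
    summary_out$reliability <- rel
  }

  # ---- regional covariate models -------------------------------------------
  if (on_stage("glm")) {
    glm_tab <- run_stage("glm", {
      design <- build_design(cohort)
      Y <- phenotype_matrix_multi(couple_out$coupling_avg)
      fit <- fit_regional_glm(Y, design, alpha = alpha)
      write_table(fit, file.path(run_dir, "glm.tsv"))
      fit
    })
    summary_out$glm_significant <-
      sum(glm_tab$significant, na.rm = TRUE)
  }

  # ---- heritability ---------------------------------------------------------
  if (on_stage("heritability")) {
    h2_tab <- run_stage("heritability", {
      h2 <- regional_heritability(
        couple_out$coupling_by_measurement, cohort, pedigree,
        covariates = c("age", "sex", "handedness"),
        region_covariates = list(sc_strength = couple_out$sc_strength,
                                 fc_strength = couple_out$fc_strength))
      write_table(h2, file.path(run_dir, "h2.tsv"))
      if (!is.null(config$subgroup_filter)) {
        keep <- eval(parse(text = config$subgroup_filter),
                     envir = as.data.frame(cohort))
        sub_ids <- cohort$subject_id[keep]
        log_line("subgroup filter '%s': %d of %d subjects",
                 config$subgroup_filter, length(sub_ids), nrow(cohort))
        cbm <- couple_out$coupling_by_measurement
        h2_sub <- regional_heritability(
          cbm[cbm$subject_id %in% sub_ids, , drop = FALSE],
          cohort[keep, , drop = FALSE],
          subset_pedigree(pedigree, sub_ids),
          covariates = c("age", "sex", "handedness"))
        write_table(h2_sub, file.path(run_dir, "h2_subgroup.tsv"))
      }
      h2
    })
    summary_out$h2_median <- stats::median(h2_tab$h2, na.rm = TRUE)
  }

  # ---- network statistics ---------------------------------------------------
  if (on_stage("netstats")) {
    ns <- run_stage("netstats", {
      coupling_mean <- group_mean(couple_out$coupling_avg)
      res <- list(
        coupling = list(
          summary = network_summary(coupling_mean, parcellation),
          contrasts = permutation_p_t(coupling_mean, parcellation,
                                      n_perm = n_perm, seed = seed + 11L)))
      if (on_stage("heritability")) {
        res$heritability <- list(
          summary = network_summary(h2_tab$h2, parcellation),
          contrasts = permutation_p_t(h2_tab$h2, parcellation,
                                      n_perm = n_perm, seed = seed + 13L))
      }
      jsonlite::write_json(res, file.path(run_dir, "netstats.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
      res
    })
    summary_out$coupling_network_medians <-
      stats::setNames(ns$coupling$summary$median,
                      ns$coupling$summary$network)
  }

  jsonlite::write_json(summary_out, file.path(run_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  log_line("run complete")
  invisible(run_dir)
}

# subjects-by-regions matrix from a phenotype table, optionally for one
# measurement index
#' @noRd
phenotype_matrix_multi <- function(tab, measurement = NULL) {
  if (!is.null(measurement)) {
    tab <- tab[tab$measurement == measurement, , drop = FALSE]
  } else if (anyDuplicated(tab$subject_id)) {
    # average over measurements
    region_cols <- setdiff(names(tab), c("subject_id", "measurement"))
    agg <- stats::aggregate(tab[region_cols],
                            by = list(subject_id = tab$subject_id),
                            FUN = mean)
    m <- as.matrix(agg[region_cols])
    rownames(m) <- agg$subject_id
    return(m)
  }
  region_cols <- setdiff(names(tab), c("subject_id", "measurement"))
  m <- as.matrix(tab[region_cols])
  rownames(m) <- tab$subject_id
  m
}
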