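#' End-to-end pipeline configuration
#'
#' Bundles the stage configurations for a reproducible run: synthetic
#' training/test libraries (or paths to real ones), the sampling plan, the
#' PCAD size, the learner, the panel threshold, the SOM configuration and
#' the alert rule file. All stage seeds derive from `seed`.
#'
#' @param out_dir run directory (created if missing).
#' @param train a [library_config()] for the training bioassay, or a file
#'   path readable by [read_library()].
#' @param test_n size of the synthetic test library (ignored when `test`
#'   is a path).
#' @param test optional path to a test library.
#' @param plan a [sample_plan()].
#' @param m PCAD size (number of prioritized descriptors).
#' @param learner a learner, e.g. [rf_learner()].
#' @param threshold panel vote threshold.
#' @param som a [som_config()].
#' @param alerts_path alert rule YAML (default: shipped demo rules).
#' @param alert_threshold demerit threshold.
#' @param n_reference number of active test compounds used as stand-in
#'   reference drugs for the SOM and panel-validation stages.
#' @param seed master seed.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("wbnscreen_run_"),
                            train = library_config(),
                            test_n = 400L, test = NULL,
                            plan = sample_plan(),
                            m = 5L,
                            learner = rf_learner(),
                            threshold = 10L,
                            som = som_config(),
                            alerts_path = NULL,
                            alert_threshold = 100L,
                            n_reference = 4L,
                            seed = 1L) {
  structure(list(out_dir = out_dir, train = train, test_n = test_n,
                 test = test, plan = plan, m = m, learner = learner,
                 threshold = threshold, som = som,
                 alerts_path = alerts_path,
                 alert_threshold = alert_threshold,
                 n_reference = n_reference, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full screening pipeline
#'
#' Stage order: descriptor generation; sampling + Z-test validation;
#' PCA prioritization; per-set model training; panel screening of the test
#' library (and of the reference compounds); SOM co-location; structural
#' alerts on the selected compounds. Stage outputs are written under
#' `config$out_dir` together with a manifest (stage, output files, MD5
#' hashes, seed, wall time).
#'
#' @param config a [pipeline_config()].
#' @return an object of class `pipeline_run`: the manifest data.frame plus
#'   the stage results (descriptor tables, `ztest_report`, `pcad_selection`,
#'   `trained_panel`, `panel_result`, SOM objects, `alert_verdict`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  results <- list()
  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    out_files <- fun()
    dt <- proc.time()[["elapsed"]] - t0
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = name,
      outputs = paste(basename(out_files), collapse = ";"),
      md5 = paste(substr(unname(tools::md5sum(out_files)), 1, 8),
                  collapse = ";"),
      seed = config$seed, wall_s = round(dt, 2),
      stringsAsFactors = FALSE)
  }
  pth <- function(f) file.path(config$out_dir, f)

  # -- stage 1: libraries and descriptor tables ---------------------------
  stage("descriptors", function() {
    if (is.character(config$train)) {
      train_mols <- read_library(config$train)
    } else {
      cfg <- config$train
      cfg$seed <- derive_seed(config$seed, 11L)
      train_mols <- generate_library(cfg)
    }
    if (!is.null(config$test)) {
      test_mols <- read_library(config$test)
    } else {
      cfg <- config$train
      cfg$n <- as.integer(config$test_n)
      cfg$seed <- derive_seed(config$seed, 12L)
      test_mols <- generate_library(cfg)
    }
    results$train_mols <<- train_mols
    results$test_mols <<- test_mols
    results$train_table <<- descriptor_table(train_mols)
    results$test_table <<- descriptor_table(test_mols)
    write_descriptor_csv(results$train_table, pth("train_descriptors.csv"))
    write_descriptor_csv(results$test_table, pth("test_descriptors.csv"))
    c(pth("train_descriptors.csv"), pth("test_descriptors.csv"))
  })

  # -- stage 2: split / mix / sample + Z-test -----------------------------
  stage("sampling", function() {
    tab <- results$train_table
    plan <- config$plan
    plan$seed <- derive_seed(config$seed, 21L)
    sets <- split_mix_sample(tab$id[tab$activity == "inactive"],
                             tab$id[tab$activity == "active"], plan)
    report <- ztest_validate(sets, tab, plan)
    results$sets <<- sets
    results$ztest <<- report
    results$training_tables <<- lapply(report$retained, function(s) {
      tab[match(sets[[s]], tab$id), , drop = FALSE]
    })
    write_ztest_csv(report, pth("ztest_report.csv"))
    writeLines(unlist(lapply(seq_along(sets), function(s)
      paste0("set", s, ",", paste(sets[[s]], collapse = ",")))),
      pth("sampled_sets.csv"))
    c(pth("ztest_report.csv"), pth("sampled_sets.csv"))
  })

  # -- stage 3: PCA prioritization ----------------------------------------
  stage("prioritize", function() {
    pca <- pca_descriptors(results$training_tables[[1]], scope = "continuous")
    sel <- select_pcad(pca, m = config$m)
    results$pca <<- pca
    results$pcad <<- sel
    write_pca_csv(pca, pth("pca_contributions.csv"))
    write_pcad(sel, pth("pcad_selection.txt"))
    c(pth("pca_contributions.csv"), pth("pcad_selection.txt"))
  })

  # -- stage 4: per-set models --------------------------------------------
  stage("train", function() {
    panel <- train_panel(results$training_tables, results$pcad$names,
                         learner = config$learner,
                         seed = derive_seed(config$seed, 41L))
    results$panel <<- panel
    write.csv(panel$metrics, pth("model_metrics.csv"), row.names = FALSE)
    pth("model_metrics.csv")
  })

  # -- stage 5: panel screening (test set + reference compounds) ----------
  stage("screen", function() {
    screen <- panel_screen(results$panel, results$test_table,
                           threshold = config$threshold)
    results$screen <<- screen
    # reference compounds: stand-in "approved drugs" drawn from the active
    # test compounds, screened through the same panel
    act <- which(results$test_table$activity == "active")
    set.seed(derive_seed(config$seed, 51L))
    ref_idx <- if (length(act)) {
      sort(sample(act, min(config$n_reference, length(act))))
    } else integer(0)
    results$reference_ids <<- results$test_table$id[ref_idx]
    if (length(ref_idx)) {
      ref_screen <- panel_screen(results$panel,
                                 results$test_table[ref_idx, , drop = FALSE],
                                 threshold = config$threshold)
      results$reference_screen <<- ref_screen
      write_panel_csv(ref_screen, pth("reference_votes.csv"))
    }
    write_panel_csv(screen, pth("panel_votes.csv"))
    c(pth("panel_votes.csv"),
      if (length(ref_idx)) pth("reference_votes.csv"))
  })

  # -- stage 6: SOM co-location -------------------------------------------
  stage("som", function() {
    sel_ids <- union(results$screen$votes$id[results$screen$votes$selected],
                     results$reference_ids)
    tab <- results$test_table[match(sel_ids, results$test_table$id), ,
                              drop = FALSE]
    feats <- results$pcad$names
    pop <- as.matrix(results$train_table[, feats, drop = FALSE])
    z <- standardize_features(as.matrix(tab[, feats, drop = FALSE]),
                              center = colMeans(pop),
                              scale = apply(pop, 2, stats::sd))
    cfg <- config$som
    cfg$seed <- derive_seed(config$seed, 61L)
    grid <- som_fit(z, cfg)
    asg <- som_assign(grid, z)
    results$som_grid <<- grid
    results$som_assignments <<- asg
    results$som_ids <<- tab$id
    results$co_location <<- if (length(results$reference_ids)) {
      co_location_report(asg, tab$id, results$reference_ids,
                         features = tab[, feats, drop = FALSE])
    }
    write_som_csv(asg, tab$id, results$reference_ids, pth("som_cells.csv"))
    pth("som_cells.csv")
  })

  # -- stage 7: structural alerts -----------------------------------------
  stage("alerts", function() {
    rules <- load_alert_rules(config$alerts_path)
    sel_ids <- results$screen$votes$id[results$screen$votes$selected]
    mols <- results$test_mols[
      vapply(results$test_mols, function(m) m$id, character(1)) %in% sel_ids]
    verdict <- if (length(mols)) {
      apply_alerts(mols, rules, threshold = config$alert_threshold)
    } else {
      apply_alerts(list(), rules)[0, ]
    }
    results$alerts <<- verdict
    results$final_ids <<- verdict$id[verdict$outcome == "pass"]
    write.csv(verdict, pth("alert_verdicts.csv"), row.names = FALSE)
    pth("alert_verdicts.csv")
  })

  manifest <- do.call(rbind, manifest)
  write.csv(manifest, file.path(config$out_dir, "manifest.csv"),
            row.names = FALSE)
  structure(c(list(manifest = manifest, out_dir = config$out_dir,
                   seed = config$seed), results),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run seed=", x$seed, ">\n", sep = "")
  print(x$manifest[, c("stage", "outputs", "wall_s")])
  invisible(x)
}
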