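#' Configuration of a full frequency-tagging experiment replica
#'
#' Bundles the simulation, spectral and inferential settings for
#' [run_experiment()]. Each named contrast gets an experimental condition
#' (oddball response scaled by the contrast's gain) and its own baseline
#' condition (no oddball response), mirroring the alternating-vs-uniform
#' sequence design. The default five contrasts carry the condition labels of
#' the linguistic hierarchy (alphabetic, readability, familiarity,
#' meaningfulness, lexicality) as abstract labels only; their default gains
#' make the first and last contrasts strong, the middle ones weak or null.
#'
#' @param sim A [sim_config()].
#' @param layout A `sensor_layout`; default [make_sensor_layout()].
#' @param n_subjects Cohort size (default 21).
#' @param trials_per_condition Trials per subject and condition (default 6).
#' @param contrasts Named numeric vector: contrast label -> oddball gain of
#'   its experimental condition.
#' @param sensor_sets Sensor analyses to run: subset of `"mag"`,
#'   `"grad_pairs"`.
#' @param adjacency_max_dist Neighbourhood distance for the sensor graphs, in
#'   meters. The default 0.035 m connects nearest-neighbour sites of the
#'   default 102-site helmet; for dense source grids a few millimeters is the
#'   appropriate scale.
#' @param baseline A [baseline_config()].
#' @param f_target Response frequency; defaults to `sim$f_odd`.
#' @param n_permutations,alpha,cluster_forming_alpha,statistic Passed to
#'   [cluster_config()].
#' @param r_scale JZS prior scale for the Bayes factor map (default 0.707).
#' @param roi Optional named character vector mapping node ids to ROI labels
#'   for the evidence tables; by default helmet quadrants
#'   (left/right x anterior/posterior) are used.
#' @param filter Optional `list(band = c(low, high), fs_new = ...)`; when
#'   `NULL` (default) the band-pass/downsample stage is skipped — synthetic
#'   epochs contain no out-of-band or aliased energy, and skipping keeps the
#'   tagged frequencies exactly bin-aligned.
#' @param seed Master seed; all stage seeds derive from it.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(sim = sim_config(), layout = NULL,
                              n_subjects = 21L, trials_per_condition = 6L,
                              contrasts = c(alphabetic = 1, readability = 0.25,
                                            familiarity = 0.25, meaningfulness = 0,
                                            lexicality = 0.75),
                              sensor_sets = c("mag", "grad_pairs"),
                              adjacency_max_dist = 0.035,
                              baseline = baseline_config(),
                              f_target = NULL,
                              n_permutations = 5000L, alpha = 0.05,
                              cluster_forming_alpha = 0.05, statistic = "mass",
                              r_scale = 0.707, roi = NULL, filter = NULL,
                              seed = 1L) {
  if (is.null(names(contrasts)) || any(!nzchar(names(contrasts)))) {
    stop("`contrasts` must be a named vector (label -> oddball gain)", call. = FALSE)
  }
  sensor_sets <- match.arg(sensor_sets, c("mag", "grad_pairs"), several.ok = TRUE)
  stopifnot_scalar_number(n_subjects, "n_subjects", positive = TRUE)
  if (n_subjects < 2) stop("n_subjects must be >= 2", call. = FALSE)
  stopifnot_scalar_number(trials_per_condition, "trials_per_condition", positive = TRUE)
  structure(list(
    sim = sim, layout = layout,
    n_subjects = as.integer(n_subjects),
    trials_per_condition = as.integer(trials_per_condition),
    contrasts = contrasts, sensor_sets = sensor_sets,
    adjacency_max_dist = adjacency_max_dist,
    baseline = baseline, f_target = f_target %||% sim$f_odd,
    n_permutations = as.integer(n_permutations), alpha = alpha,
    cluster_forming_alpha = cluster_forming_alpha, statistic = statistic,
    r_scale = r_scale, roi = roi, filter = filter, seed = as.integer(seed)
  ), class = "experiment_config")
}

#' Load an experiment configuration from YAML
#'
#' Top-level keys mirror the arguments of [experiment_config()]; the `sim`
#' key holds [sim_config()] arguments. Unknown keys raise an error.
#'
#' @param path YAML file.
#' @return An `experiment_config`.
#' @export
experiment_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  for (nm in c("base_amplitudes", "odd_amplitudes")) {
    if (!is.null(sim_args[[nm]])) sim_args[[nm]] <- unlist(sim_args[[nm]])
  }
  for (nm in c("base_topography", "odd_topography")) {
    if (!is.null(sim_args[[nm]])) {
      sim_args[[nm]]$center <- as.numeric(unlist(sim_args[[nm]]$center))
    }
  }
  y$sim <- NULL
  if (!is.null(y$contrasts)) y$contrasts <- unlist(y$contrasts)
  if (!is.null(y$layout_csv)) {
    y$layout <- read_sensor_layout(y$layout_csv)
    y$layout_csv <- NULL
  }
  known <- names(formals(experiment_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ","), call. = FALSE)
  do.call(experiment_config, c(list(sim = do.call(sim_config, sim_args)), y))
}

# Helmet-quadrant ROI labels from node positions.
quadrant_rois <- function(pos) {
  lab <- paste0(ifelse(pos[, 1] < 0, "left_", "right_"),
                ifelse(pos[, 2] < 0, "posterior", "anterior"))
  stats::setNames(lab, rownames(pos))
}

#' Run the full simulate-analyze-report pipeline
#'
#' For every contrast, simulates the cohort's experimental and baseline
#' conditions (per-subject amplitude scalings and one shared set of harmonic
#' phases, all derived from the master seed), computes per-subject
#' trial-averaged amplitude spectra, baseline-corrects them and extracts the
#' oddball response, then runs the paired cluster permutation test per sensor
#' set, computes Hedges g per cluster, and a JZS Bayes factor per node with
#' ROI-wise evidence tabulation. Epochs are simulated one subject x condition
#' at a time and discarded after their spectrum is taken, keeping memory flat.
#'
#' When `out_dir` is given, writes `responses.tsv`, `clusters.json`,
#' `effect_sizes.tsv`, `bf.tsv`, `evidence.tsv`, `summary.tsv`,
#' `tables.md`, `config.json` and `manifest.json` (stage seeds, package
#' version, file checksums). Re-running with the same config and seed
#' reproduces these files byte-identically.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional output directory (created if missing).
#' @param quiet Suppress progress messages (default FALSE).
#' @return An `fpvs_experiment` result list: `responses`, `stats` (per
#'   contrast x sensor set: `cluster_result`, effect sizes, BF map, evidence
#'   table), `summary` data frame, `tables`, `manifest`.
#' @export
run_experiment <- function(config, out_dir = NULL, quiet = FALSE) {
  if (!inherits(config, "experiment_config")) {
    stop("`config` must be an experiment_config", call. = FALSE)
  }
  say <- function(...) if (!quiet) message(sprintf(...))
  layout <- config$layout %||% make_sensor_layout()
  seed <- config$seed
  scfg <- config$sim
  scfg$phase_seed <- derive_seed(seed, 1L)
  scales <- cohort_subject_scales(scfg, config$n_subjects, seed)
  subjects <- sprintf("sub%02d", seq_len(config$n_subjects))

  graphs <- lapply(config$sensor_sets, function(k) {
    build_adjacency(layout, config$adjacency_max_dist, kind = k)
  })
  names(graphs) <- config$sensor_sets
  rois <- lapply(config$sensor_sets, function(k) {
    config$roi %||% quadrant_rois(layout_positions(layout, k))
  })
  names(rois) <- config$sensor_sets

  mag_ids <- layout$sensor_id[layout$kind == "mag"]
  contrast_names <- names(config$contrasts)
  responses <- list()
  stats_out <- list()
  summary_rows <- list()

  for (ci in seq_along(contrast_names)) {
    cname <- contrast_names[ci]
    gain <- unname(config$contrasts[ci])
    say("contrast '%s' (oddball gain %g): simulating %d subjects", cname, gain, config$n_subjects)
    resp <- list()
    for (set in config$sensor_sets) {
      resp[[set]] <- list(exp = NULL, base = NULL)
    }
    for (s in seq_len(config$n_subjects)) {
      for (cond in c("exp", "base")) {
        ccfg <- condition_config(scfg, condition_spec(
          label = cond,
          type = if (cond == "exp") "experimental" else "baseline",
          odd_gain = gain
        ))
        ep <- simulate_trial_average(
          ccfg, layout,
          condition = if (cond == "exp") "experimental" else "baseline",
          seed = derive_seed(seed, 100000L + ci * 1000L + s * 10L + (cond == "exp")),
          subject_scale = scales[s],
          n_trials = config$trials_per_condition
        )
        if (!is.null(config$filter)) {
          ep <- filter_and_downsample(ep, band = config$filter$band,
                                      fs_new = config$filter$fs_new)
        }
        sp <- compute_spectrum(ep)
        for (set in config$sensor_sets) {
          sp_set <- if (set == "mag") {
            structure(list(amplitudes = sp$amplitudes[mag_ids, , drop = FALSE],
                           freqs = sp$freqs, resolution = sp$resolution,
                           corrected = FALSE), class = "amplitude_spectrum")
          } else {
            combine_planar(sp, layout)
          }
          bin <- which.min(abs(sp_set$freqs - config$f_target))
          bc <- baseline_correct(sp_set, config$baseline, bins = bin)
          rmap <- extract_response(bc, config$f_target,
                                   subject_id = subjects[s],
                                   condition = paste0(cname, "_", cond))
          resp[[set]][[cond]] <- rbind(resp[[set]][[cond]],
                                       matrix(rmap$values, nrow = 1,
                                              dimnames = list(subjects[s], names(rmap$values))))
        }
      }
    }
    responses[[cname]] <- resp

    stats_out[[cname]] <- list()
    for (si in seq_along(config$sensor_sets)) {
      set <- config$sensor_sets[si]
      ccfg <- cluster_config(
        n_permutations = config$n_permutations, alpha = config$alpha,
        cluster_forming_alpha = config$cluster_forming_alpha,
        statistic = config$statistic,
        seed = derive_seed(seed, 200000L + ci * 100L + si)
      )
      cres <- suppressMessages(
        cluster_permutation_test(resp[[set]]$exp, resp[[set]]$base, graphs[[set]], ccfg)
      )
      d <- resp[[set]]$exp - resp[[set]]$base
      effects <- lapply(cres$clusters, function(cl) {
        hedges_g(rowMeans(d[, cl$members, drop = FALSE]))
      })
      tmap <- cres$t_map
      ok <- !is.na(tmap)
      bf <- rep(NA_real_, length(tmap))
      names(bf) <- names(tmap)
      bf[ok] <- vapply(tmap[ok], function(tt) {
        jzs_bf10(tt, n = nrow(d), r_scale = config$r_scale)$bf10
      }, numeric(1))
      ev <- tabulate_evidence(bf[ok], rois[[set]])
      stats_out[[cname]][[set]] <- list(
        cluster = cres, effects = effects, bf = bf, evidence = ev
      )
      sig <- vapply(cres$clusters, `[[`, logical(1), "significant")
      top <- if (length(cres$clusters)) cres$clusters[[1]] else NULL
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        contrast = cname, sensor_set = set,
        n_clusters = length(cres$clusters),
        any_significant = any(sig),
        min_p = if (length(cres$clusters)) min(vapply(cres$clusters, `[[`, numeric(1), "p")) else NA_real_,
        max_mass = if (!is.null(top)) top$mass else NA_real_,
        g = if (length(effects)) effects[[1]]$g else NA_real_,
        ci_low = if (length(effects)) effects[[1]]$ci_low else NA_real_,
        ci_high = if (length(effects)) effects[[1]]$ci_high else NA_real_,
        stringsAsFactors = FALSE
      )
      say("  %s: %d cluster(s), %s", set, length(cres$clusters),
          if (any(sig)) sprintf("min p = %.4g *", min(vapply(cres$clusters, `[[`, numeric(1), "p")))
          else "none significant")
    }
  }

  summary_df <- if (length(summary_rows)) do.call(rbind, summary_rows) else
    data.frame(contrast = character(), sensor_set = character(), n_clusters = integer(),
               any_significant = logical(), min_p = numeric(), max_mass = numeric(),
               g = numeric(), ci_low = numeric(), ci_high = numeric())

  result <- structure(list(
    config = config, responses = responses, stats = stats_out,
    summary = summary_df, subject_scales = stats::setNames(scales, subjects),
    graphs = graphs
  ), class = "fpvs_experiment")
  result$tables <- report_tables(result)

  if (!is.null(out_dir)) {
    result$manifest <- write_experiment_outputs(result, out_dir)
  }
  result
}

#' @export
print.fpvs_experiment <- function(x, ...) {
  cat(sprintf("<fpvs_experiment> %d contrast(s) x %d sensor set(s), %d subjects\n",
              length(x$stats), length(x$config$sensor_sets), x$config$n_subjects))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Assemble report tables from experiment results
#'
#' Builds (i) a cluster table — one row per contrast x sensor set x cluster
#' with the mass statistic, Monte Carlo p and Hedges g with CI — and (ii) the
#' ROI evidence table with vertex counts and the numbers (and integer
#' percentages) of nodes with `BF10 < 1/3` and `BF10 > 3`. Empty results give
#' header-only tables.
#'
#' @param results An `fpvs_experiment` (or a list with a `stats` element of
#'   the same shape).
#' @return List with `cluster_table`, `evidence_table` (data frames) and
#'   `markdown` (character vector of Markdown lines).
#' @export
report_tables <- function(results) {
  empty_cluster <- data.frame(
    contrast = character(), sensor_set = character(), cluster = integer(),
    n_nodes = integer(), mass = numeric(), p = numeric(), significant = logical(),
    g = numeric(), ci_low = numeric(), ci_high = numeric(), stringsAsFactors = FALSE
  )
  empty_evidence <- data.frame(
    contrast = character(), sensor_set = character(), roi = character(),
    n_vertices = integer(), n_bf_below_third = integer(), pct_below_third = integer(),
    n_bf_above_three = integer(), pct_above_three = integer(), stringsAsFactors = FALSE
  )
  cl_rows <- list()
  ev_rows <- list()
  for (cname in names(results$stats)) {
    for (set in names(results$stats[[cname]])) {
      st <- results$stats[[cname]][[set]]
      for (k in seq_along(st$cluster$clusters)) {
        cl <- st$cluster$clusters[[k]]
        es <- st$effects[[k]]
        cl_rows[[length(cl_rows) + 1L]] <- data.frame(
          contrast = cname, sensor_set = set, cluster = k,
          n_nodes = length(cl$members), mass = cl$mass, p = cl$p,
          significant = cl$significant,
          g = es$g, ci_low = es$ci_low, ci_high = es$ci_high,
          stringsAsFactors = FALSE
        )
      }
      ev <- st$evidence
      if (nrow(ev)) {
        ev_rows[[length(ev_rows) + 1L]] <- cbind(
          data.frame(contrast = cname, sensor_set = set, stringsAsFactors = FALSE),
          as.data.frame(ev)
        )
      }
    }
  }
  cluster_table <- if (length(cl_rows)) do.call(rbind, cl_rows) else empty_cluster
  evidence_table <- if (length(ev_rows)) do.call(rbind, ev_rows) else empty_evidence

  md <- c(
    "## Cluster results", "",
    df_to_markdown(cluster_table), "",
    "## Bayes factor evidence by ROI", "",
    df_to_markdown(evidence_table)
  )
  list(cluster_table = cluster_table, evidence_table = evidence_table, markdown = md)
}

df_to_markdown <- function(df) {
  fmt <- function(x) {
    if (is.numeric(x)) vapply(x, function(v) {
      if (is.na(v)) "" else if (v == round(v) && abs(v) < 1e15) sprintf("%d", as.integer(v))
      else sprintf("%.4g", v)
    }, character(1)) else as.character(x)
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L, dimnames = list(NULL, names(df)))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  if (!nrow(df)) return(c(header, sep))
  body <- apply(cells, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}

write_experiment_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config <- result$config
  paths <- character()

  # tidy responses
  resp_rows <- list()
  for (cname in names(result$responses)) {
    for (set in names(result$responses[[cname]])) {
      for (cond in c("exp", "base")) {
        m <- result$responses[[cname]][[set]][[cond]]
        resp_rows[[length(resp_rows) + 1L]] <- data.frame(
          contrast = cname, sensor_set = set, condition = cond,
          subject = rep(rownames(m), times = ncol(m)),
          node = rep(colnames(m), each = nrow(m)),
          f_target = config$f_target, value = as.numeric(m),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  p <- file.path(out_dir, "responses.tsv")
  utils::write.table(do.call(rbind, resp_rows), p, sep = "\t", row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)

  # clusters as JSON
  cl_json <- lapply(result$stats, function(by_set) {
    lapply(by_set, function(st) {
      lapply(st$cluster$clusters, function(cl) {
        list(members = cl$members, mass = cl$mass, p = cl$p, significant = cl$significant)
      })
    })
  })
  p <- file.path(out_dir, "clusters.json")
  jsonlite::write_json(cl_json, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, p)

  p <- file.path(out_dir, "effect_sizes.tsv")
  utils::write.table(result$tables$cluster_table, p, sep = "\t", row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)

  bf_rows <- list()
  for (cname in names(result$stats)) {
    for (set in names(result$stats[[cname]])) {
      st <- result$stats[[cname]][[set]]
      ok <- !is.na(st$bf)
      bf_rows[[length(bf_rows) + 1L]] <- data.frame(
        contrast = cname, sensor_set = set, node = names(st$bf)[ok],
        t = unname(st$cluster$t_map[ok]), bf10 = unname(st$bf[ok]),
        evidence = classify_evidence(st$bf[ok]), stringsAsFactors = FALSE
      )
    }
  }
  p <- file.path(out_dir, "bf.tsv")
  utils::write.table(do.call(rbind, bf_rows), p, sep = "\t", row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)

  p <- file.path(out_dir, "evidence.tsv")
  utils::write.table(result$tables$evidence_table, p, sep = "\t", row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)

  p <- file.path(out_dir, "summary.tsv")
  utils::write.table(result$summary, p, sep = "\t", row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)

  p <- file.path(out_dir, "tables.md")
  writeLines(result$tables$markdown, p)
  paths <- c(paths, p)

  cfg_json <- unclass(config)
  cfg_json$layout <- if (is.null(config$layout)) "default_306" else "user_supplied"
  cfg_json$sim <- unclass(config$sim)
  cfg_json$baseline <- unclass(config$baseline)
  p <- file.path(out_dir, "config.json")
  jsonlite::write_json(cfg_json, p, auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  paths <- c(paths, p)

  checksums <- tools::md5sum(paths)
  names(checksums) <- basename(names(checksums))
  manifest <- list(
    package_version = as.character(utils::packageVersion("fpvstag")),
    master_seed = config$seed,
    stage_seeds = list(phase_seed = derive_seed(config$seed, 1L),
                       subject_scales_seed = derive_seed(config$seed, 0L)),
    config_md5 = unname(checksums[["config.json"]]),
    file_md5 = as.list(checksums)
  )
  p <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}
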