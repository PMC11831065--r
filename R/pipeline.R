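#' Pipeline configuration
#'
#' Bundles every stage's parameters: the synthetic-cohort block (or a
#' list of already-loaded recordings), preprocessing, Welch estimation,
#' band definitions, graph thresholds and the FDR cutoff.
#'
#' @param simulate A [synth_config()], or `NULL` when `recordings` is
#'   given.
#' @param recordings Optional list of [recording()]s to analyse instead
#'   of simulating.
#' @param preprocess A [preprocess_config()].
#' @param welch A [welch_config()].
#' @param bands Band tibble, default [eeg_bands()].
#' @param thresholds Coherence cutoffs for group graphs.
#' @param q_cutoff FDR significance cutoff.
#' @param output_dir Optional directory for TSV/JSON artifacts.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(simulate = NULL, recordings = NULL,
                            preprocess = preprocess_config(),
                            welch = welch_config(), bands = eeg_bands(),
                            thresholds = c(0.5, 0.7), q_cutoff = 0.05,
                            output_dir = NULL) {
  if (is.null(simulate) && is.null(recordings)) {
    abort("Provide either a `simulate` block or `recordings`.")
  }
  structure(list(simulate = simulate, recordings = recordings,
                 preprocess = preprocess, welch = welch, bands = bands,
                 thresholds = thresholds, q_cutoff = q_cutoff,
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Demo source set with a planted alpha3 frontal deficit
#'
#' Three shared narrowband sources on the 32-channel fixture montage:
#' an upper-alpha source centred at 12 Hz (confined well inside the
#' 11--13 Hz alpha3 band so its coupling does not spill across band
#' boundaries) over right-frontal and frontal-midline channels, present
#' in the eyes-open condition only and attenuated in the case group by
#' `deficit_scale` (the planted connectivity deficit); a
#' 9--11 Hz occipital alpha source, stronger with eyes closed (alpha
#' blocking) and identical across groups; and a 5--7 Hz fronto-midline
#' theta source, identical across groups and conditions.
#'
#' @param deficit_scale Case-group gain multiplier on the 11--13 Hz
#'   source (1 = no planted difference; 0.4 = a 60% reduction).
#' @return List of [source_spec()]s.
#' @export
demo_sources <- function(deficit_scale = 0.4) {
  list(
    source_spec(center_freq = 12, bandwidth = 0.5,
                target_channels = c("Fp2", "AF4", "F4", "F8", "FC6", "Fz", "Cz"),
                gain = 4.5,
                group_gain_scale = c(case = deficit_scale, control = 1),
                condition_gain_scale = c(EO = 1, EC = 0)),
    source_spec(center_freq = 10, bandwidth = 2,
                target_channels = c("PO3", "PO4", "O1", "Oz", "O2"),
                gain = 2.5,
                group_gain_scale = c(case = 1, control = 1),
                condition_gain_scale = c(EO = 0.5, EC = 1)),
    source_spec(center_freq = 6, bandwidth = 2,
                target_channels = c("Fz", "Cz", "Pz"),
                gain = 1.5,
                group_gain_scale = c(case = 1, control = 1),
                condition_gain_scale = c(EO = 1, EC = 1)))
}

#' Channels targeted by the planted deficit source
#' @return Character vector of fixture-montage labels.
#' @export
deficit_targets <- function() c("Fp2", "AF4", "F4", "F8", "FC6", "Fz", "Cz")

#' Ready-made demo / null pipeline configurations
#'
#' `demo_config()` reproduces the study design at desk scale: two
#' groups of `n_per_group` subjects, 32 channels, 2 conditions x 3 x
#' 60-s annotated intervals at 250 Hz (56-s analysis epochs after the
#' 4-s lead discard), with the planted alpha3 frontal deficit of
#' [demo_sources()]. `null_config()` is identical except
#' `deficit_scale = 1`, making the two groups statistically
#' exchangeable.
#'
#' @param n_per_group Subjects per group.
#' @param seed Master seed.
#' @param deficit_scale See [demo_sources()].
#' @param ... Passed on to [synth_config()] (e.g. `epoch_s`,
#'   `n_epochs`, `montage`).
#' @return A [pipeline_config()].
#' @export
demo_config <- function(n_per_group = 12, seed = 7, deficit_scale = 0.4, ...) {
  pipeline_config(simulate = synth_config(
    montage = fixture_montage(), n_per_group = n_per_group,
    sources = demo_sources(deficit_scale), seed = seed, ...))
}

#' @rdname demo_config
#' @export
null_config <- function(n_per_group = 12, seed = 7, ...) {
  demo_config(n_per_group = n_per_group, seed = seed, deficit_scale = 1, ...)
}

#' Validate a pipeline configuration
#'
#' Returns all detected issues (empty character vector when the
#' configuration is sound): bands that would be empty on the Welch
#' frequency grid, bands that partially overlap (bands must be nested
#' or disjoint so sub-bands partition their parent), thresholds or
#' cutoffs out of range.
#'
#' @param cfg A [pipeline_config()].
#' @return Character vector of issue descriptions.
#' @export
validate_config <- function(cfg) {
  issues <- character()
  bands <- cfg$bands
  if (!nrow(bands)) issues <- c(issues, "No frequency bands defined.")
  if (any(bands$low <= 0) || any(bands$high <= bands$low)) {
    issues <- c(issues, "Bands must satisfy 0 < low < high.")
  }
  fs <- if (!is.null(cfg$simulate)) cfg$simulate$fs
        else if (length(cfg$recordings)) cfg$recordings[[1]]$fs else NULL
  if (!is.null(fs)) {
    df <- fs / round(cfg$welch$segment_s * fs)  # the realised Welch grid
    grid <- seq(0, fs / 2, by = df)
    for (b in seq_len(nrow(bands))) {
      if (!any(grid >= bands$low[b] & grid < bands$high[b])) {
        issues <- c(issues, sprintf(
          "Band %s [%g, %g) has no bin at Welch resolution %g Hz.",
          bands$band[b], bands$low[b], bands$high[b], df))
      }
    }
    if (fs <= 2 * cfg$preprocess$lowpass) {
      issues <- c(issues, "Sampling rate must exceed twice the low-pass edge.")
    }
  }
  if (nrow(bands) > 1) {
    for (a in seq_len(nrow(bands) - 1)) {
      for (b in (a + 1):nrow(bands)) {
        lo <- max(bands$low[a], bands$low[b])
        hi <- min(bands$high[a], bands$high[b])
        nested <- (bands$low[a] >= bands$low[b] && bands$high[a] <= bands$high[b]) ||
                  (bands$low[b] >= bands$low[a] && bands$high[b] <= bands$high[a])
        if (lo < hi && !nested) {
          issues <- c(issues, sprintf(
            "Bands %s and %s partially overlap; bands must be nested or disjoint.",
            bands$band[a], bands$band[b]))
        }
      }
    }
  }
  if (any(cfg$thresholds < 0 | cfg$thresholds > 1)) {
    issues <- c(issues, "Graph thresholds must lie in [0, 1].")
  }
  if (cfg$q_cutoff <= 0 || cfg$q_cutoff >= 1) {
    issues <- c(issues, "`q_cutoff` must lie in (0, 1).")
  }
  issues
}

#' Run the full connectivity pipeline
#'
#' simulate (or load) -> preprocess -> Welch coherence -> edge-wise
#' Mann-Whitney + BH -> median group graphs and difference graphs ->
#' region summaries -> run report. Deterministic given the simulate
#' seed. When `cfg$output_dir` is set, profiles, edge tests, graph edge
#' lists and the JSON report are written there.
#'
#' @param cfg A [pipeline_config()].
#' @return An object of class `"coherence_run"`: list with `report`
#'   (one row per band x condition: pair and significance counts),
#'   `tests`, `profiles`, `graphs` (per cell x group x threshold),
#'   `difference_graphs`, `region_summaries`, `montage`, `config`,
#'   `provenance`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  issues <- validate_config(cfg)
  if (length(issues)) {
    abort(paste0("Invalid pipeline config:\n", paste("-", issues, collapse = "\n")))
  }
  recs <- cfg$recordings %||% NULL
  if (is.null(recs)) recs <- generate_cohort(cfg$simulate)
  mon <- if (!is.null(cfg$simulate)) cfg$simulate$montage else recs[[1]]$montage

  profiles <- cohort_coherence(recs, cfg$preprocess, cfg$welch, cfg$bands)
  tests <- edgewise_comparison(profiles)

  cells <- dplyr::distinct(tests, .data$band, .data$condition)
  graphs <- list(); diffs <- list(); regions <- list()
  report <- vector("list", nrow(cells))
  for (k in seq_len(nrow(cells))) {
    b <- cells$band[k]; cond <- cells$condition[k]
    cell_tests <- tests[tests$band == b & tests$condition == cond, ]
    dg <- difference_graph(cell_tests, cfg$q_cutoff)
    key <- paste(b, cond, sep = ".")
    diffs[[key]] <- dg
    regions[[key]] <- region_summary(dg, mon)
    for (g in c("case", "control")) {
      med <- group_median(profiles, g, cond, b)
      for (thr in cfg$thresholds) {
        graphs[[paste(key, g, thr, sep = ".")]] <-
          threshold_graph(med, thr, group = g, condition = cond, band = b)
      }
    }
    report[[k]] <- tibble::tibble(
      band = b, condition = cond, n_pairs = nrow(cell_tests),
      n_sig = sum(cell_tests$q <= cfg$q_cutoff),
      n_deficit = nrow(dg$edges), n_excess = nrow(dg$excess_edges))
  }
  report <- dplyr::bind_rows(report)

  cfg_for_hash <- cfg
  cfg_for_hash$output_dir <- NULL
  provenance <- list(
    config_hash = rlang::hash(cfg_for_hash),
    seed = if (!is.null(cfg$simulate)) cfg$simulate$seed else NA_integer_,
    package_version = as.character(packageVersion("coherenet")),
    q_cutoff = cfg$q_cutoff, thresholds = cfg$thresholds)

  run <- structure(list(report = report, tests = tests, profiles = profiles,
                        graphs = graphs, difference_graphs = diffs,
                        region_summaries = regions, montage = mon,
                        config = cfg, provenance = provenance),
                   class = "coherence_run")
  if (!is.null(cfg$output_dir)) write_run(run, cfg$output_dir)
  run
}

write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(run$profiles, "coherence_profiles.tsv")
  tsv(run$tests, "edge_tests.tsv")
  tsv(run$report, "run_report.tsv")
  graph_edges <- purrr::imap(run$graphs, function(g, nm) {
    dplyr::mutate(g$edges, band = g$band, condition = g$condition,
                  group = g$group, threshold = g$threshold)
  }) |> dplyr::bind_rows()
  tsv(graph_edges, "group_graph_edges.tsv")
  jsonlite::write_json(
    list(provenance = run$provenance, report = run$report),
    file.path(dir, "run_report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.coherence_run <- function(x, ...) {
  cat(sprintf("<coherence_run> %d subjects, %d band x condition cells, q cutoff %g\n",
              length(unique(x$profiles$subject_id)), nrow(x$report),
              x$provenance$q_cutoff))
  sig <- x$report[x$report$n_sig > 0, ]
  if (nrow(sig)) {
    cat("Cells with FDR-significant edges:\n")
    print(as.data.frame(sig), row.names = FALSE)
  } else {
    cat("No FDR-significant edges in any cell.\n")
  }
  invisible(x)
}

#' @export
tidy.coherence_run <- function(x, ...) x$tests

#' One-row summary of a pipeline run
#' @param x A `coherence_run`.
#' @param ... Unused.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @export
glance.coherence_run <- function(x, ...) {
  tibble::tibble(
    n_subjects = length(unique(x$profiles$subject_id)),
    n_cells = nrow(x$report),
    n_pairs = x$report$n_pairs[1],
    n_sig_total = sum(x$report$n_sig),
    n_deficit_total = sum(x$report$n_deficit),
    q_cutoff = x$provenance$q_cutoff,
    seed = x$provenance$seed,
    config_hash = x$provenance$config_hash)
}

#' Read a pipeline configuration from YAML
#'
#' Expects top-level blocks `simulate` (fields of [synth_config()],
#' with `montage: fixture` or `montage: <n>` and `sources:` given as
#' lists of [source_spec()] fields, or the shorthand
#' `sources: demo` / `deficit_scale:`), `preprocess`, `welch`,
#' and scalars `thresholds`, `q_cutoff`, `output_dir`.
#'
#' @param path Path to a YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulate) && !identical(y$simulate, "off")) {
    s <- y$simulate
    mon <- s$montage %||% "fixture"
    mon <- if (identical(mon, "fixture")) fixture_montage()
           else schematic_montage(as.integer(mon))
    sources <- if (identical(s$sources %||% "demo", "demo")) {
      demo_sources(s$deficit_scale %||% 0.4)
    } else {
      lapply(s$sources, function(sp) source_spec(
        center_freq = sp$center_freq, bandwidth = sp$bandwidth,
        target_channels = unlist(sp$target_channels), gain = sp$gain %||% 1,
        group_gain_scale = unlist(sp$group_gain_scale %||%
                                    list(case = 1, control = 1)),
        condition_gain_scale = unlist(sp$condition_gain_scale %||%
                                        list(EO = 1, EC = 1))))
    }
    args <- s[intersect(names(s), c("n_per_group", "noise_exponent",
                                    "noise_sd", "fs", "epoch_s", "n_epochs",
                                    "gain_jitter_sd", "seed"))]
    sim <- do.call(synth_config, c(list(montage = mon, sources = sources), args))
  }
  pp <- do.call(preprocess_config, y$preprocess %||% list())
  wc <- do.call(welch_config, y$welch %||% list())
  pipeline_config(simulate = sim, preprocess = pp, welch = wc,
                  thresholds = unlist(y$thresholds %||% c(0.5, 0.7)),
                  q_cutoff = y$q_cutoff %||% 0.05,
                  output_dir = y$output_dir)
}
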