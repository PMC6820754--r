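#' Default pipeline configuration
#'
#' Returns the full parameter set of the analysis as a named list, with the
#' signal-conditioning and statistical defaults of a broadband (0.5-35 Hz)
#' resting-state pipeline: forward 0.5 Hz high-pass, 50 Hz notch, zero-phase
#' 35 Hz low-pass, 8 pseudo-random epochs of 8 s excluding the first minute,
#' pTE with embedding 1 and 49 histogram bins per axis with the delay
#' estimated from the phase sign-flip rate, 5000 permutations, FDR q =
#' 0.001. Any entry can be overridden through `...` or by the `config`
#' argument of [run_pipeline()].
#'
#' @param ... Named overrides.
#' @return Named list of parameters.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    fs = 600,
    highpass_hz = 0.5, notch_hz = 50, lowpass_hz = 35,
    filter_order = 4, notch_q = 30,
    n_epochs = 8, epoch_seconds = 8, exclude_seconds = 60,
    bins = 49L, bin_mode = "paper_fixed", delay = NULL,
    n_permutations = 5000, fdr_q = 0.001,
    swp_n_random = 50,
    seed = 1L,
    surrogate_control = FALSE,
    out_dir = NULL,
    simulate = NULL
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

validate_pipeline_config <- function(cfg) {
  required <- c("fs", "n_epochs", "epoch_seconds", "bins", "n_permutations",
                "fdr_q", "seed")
  missing <- required[!vapply(required, function(k) {
    !is.null(cfg[[k]]) && is.finite(as.numeric(cfg[[k]]))
  }, TRUE)]
  if (length(missing)) {
    stop("pipeline config is missing or non-numeric: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(cfg)
}

pipeline_stage <- function(name, verbose) {
  t0 <- Sys.time()
  if (verbose) message("[", name, "] ...")
  function() {
    if (verbose) {
      message("[", name, "] done in ",
              sprintf("%.1f", as.numeric(Sys.time() - t0, units = "secs")),
              " s")
    }
  }
}

#' Run the full directed-connectivity pipeline
#'
#' Executes simulate (optional) -> filter -> epoch -> pTE -> subject
#' connectomes -> within-group sign-flip networks -> between-group label
#' permutation -> FDR -> significant networks -> graph metrics -> group
#' comparisons and behavioral correlations. All randomness derives from
#' `config$seed`, so rerunning the same configuration reproduces every
#' number.
#'
#' @param config A [pipeline_config()] list (or a YAML file path).
#' @param cohort A [simulate_cohort()] object; if `NULL`, `config$simulate`
#'   (a list with `n_nodes`, `n_edges_common`, `n_edges_patient_extra`,
#'   `strength_patient_extra`, `n_per_group`, `duration`) is used to build
#'   one.
#' @param verbose Log stage progress and timings.
#' @return A `pipeline_report` list: subject table with metrics, the two
#'   group networks, the group-difference network, comparisons,
#'   correlations, connectomes, masks and the run manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL,
                         verbose = TRUE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_pipeline_config(config)
  cfg <- config

  if (is.null(cohort)) {
    if (is.null(cfg$simulate)) {
      stop("no cohort supplied and config$simulate is empty", call. = FALSE)
    }
    done <- pipeline_stage("simulate", verbose)
    sim <- cfg$simulate
    spec_c <- make_coupling_spec(sim$n_nodes, sim$n_edges_common,
                                 seed = cfg$seed + 11L)
    extra <- make_coupling_spec(sim$n_nodes, sim$n_edges_patient_extra,
                                strength_range =
                                  rep(sim$strength_patient_extra, 2),
                                seed = cfg$seed + 12L)
    # patient group = control couplings plus the extra planted edges
    both <- rbind(spec_c$edges, extra$edges)
    both <- both[!duplicated(both[c("source", "target")]), ]
    spec_p <- spec_c
    spec_p$edges <- both
    cohort <- simulate_cohort(spec_c, spec_p, sim$n_per_group,
                              sim$duration, cfg$fs, seed = cfg$seed)
    done()
  }

  done <- pipeline_stage("preprocess", verbose)
  epoch_sets <- lapply(seq_along(cohort$series), function(i) {
    filt <- apply_filters(cohort$series[[i]],
                          highpass_hz = cfg$highpass_hz,
                          notch_hz = cfg$notch_hz,
                          lowpass_hz = cfg$lowpass_hz,
                          order = cfg$filter_order, notch_q = cfg$notch_q)
    segment_epochs(filt, n_epochs = cfg$n_epochs,
                   epoch_seconds = cfg$epoch_seconds,
                   exclude_seconds = cfg$exclude_seconds,
                   seed = cfg$seed + 100L + i)
  })
  done()

  done <- pipeline_stage("pte", verbose)
  params <- pte_params(delay = cfg$delay, bins = cfg$bins)
  connectomes <- lapply(seq_along(epoch_sets), function(i) {
    es <- epoch_sets[[i]]
    epochs <- es$epochs
    if (isTRUE(cfg$surrogate_control)) {
      epochs <- lapply(seq_along(epochs), function(k) {
        phase_randomized_surrogate(epochs[[k]],
                                   seed = cfg$seed + 1000L + 100L * i + k)
      })
    }
    per_epoch <- lapply(epochs, function(e) {
      pte_adjacency(instantaneous_phase(e, es$fs), params)
    })
    subject_connectome(per_epoch)
  })
  done()

  groups <- cohort$subjects$group
  conn_c <- connectomes[groups == "control"]
  conn_p <- connectomes[groups == "patient"]

  done <- pipeline_stage("group-stats", verbose)
  stats_c <- edgewise_one_sample_test(conn_c, cfg$n_permutations,
                                      seed = cfg$seed + 21L)
  stats_p <- edgewise_one_sample_test(conn_p, cfg$n_permutations,
                                      seed = cfg$seed + 22L)
  stats_diff <- edgewise_two_sample_test(conn_p, conn_c, cfg$n_permutations,
                                         seed = cfg$seed + 23L)
  mask_c <- fdr_threshold(stats_c$p, cfg$fdr_q)
  mask_p <- fdr_threshold(stats_p$p, cfg$fdr_q)
  mask_diff <- fdr_threshold(stats_diff$p, cfg$fdr_q)
  net_c <- extract_significant_network(stats_c, mask_c, cfg$fdr_q)
  net_p <- extract_significant_network(stats_p, mask_p, cfg$fdr_q)
  net_diff <- extract_significant_network(stats_diff, mask_diff, cfg$fdr_q)
  done()

  n_nodes_total <- nrow(stats_c$t)
  density_vals <- vapply(list(net_c, net_p, net_diff), function(net) {
    network_density(n_nodes_total, nrow(net$edges))
  }, 0)
  density <- tibble::tibble(
    group = c("control", "patient", "difference"),
    n_nodes = c(length(net_c$nodes), length(net_p$nodes),
                length(net_diff$nodes)),
    n_edges = c(nrow(net_c$edges), nrow(net_p$edges), nrow(net_diff$edges)),
    density = density_vals
  )

  done <- pipeline_stage("graph-metrics", verbose)
  union_mask <- mask_c | mask_p
  subjects <- cohort$subjects
  metrics <- NULL
  if (any(union_mask)) {
    metrics <- tryCatch(
      dplyr::bind_rows(lapply(seq_along(connectomes), function(i) {
        subject_graph_metrics(connectomes[[i]], union_mask,
                              seed = cfg$seed + 30L)
      })),
      error = function(e) {
        message("graph metrics skipped: ", conditionMessage(e))
        NULL
      })
  }
  if (!is.null(metrics)) {
    subjects <- dplyr::bind_cols(subjects,
                                 metrics[c("swp", "efficiency", "cpl")])
    comparisons <- dplyr::bind_rows(lapply(
      c("swp", "efficiency", "cpl"),
      function(mname) {
        compare_group_metrics(subjects[[mname]][groups == "patient"],
                              subjects[[mname]][groups == "control"],
                              metric = mname)
      }))
    score_cols <- intersect(c("THI", "VAS_loudness", "VAS_distress",
                              "VAS_handicap", "hearing_loss"),
                            names(subjects))
    pat <- subjects[groups == "patient", ]
    correlations <- dplyr::bind_rows(lapply(
      c("swp", "efficiency", "cpl"),
      function(mname) {
        dplyr::bind_rows(lapply(score_cols, function(sname) {
          if (sd(pat[[sname]]) == 0 || sd(pat[[mname]]) == 0) return(NULL)
          correlate_metrics_with_scores(pat[[mname]], pat[[sname]],
                                        metric_name = mname,
                                        score_name = sname)
        }))
      }))
  } else {
    comparisons <- correlations <- tibble::tibble()
  }
  done()

  manifest <- list(
    package = "ptenet",
    version = as.character(utils::packageVersion("ptenet")),
    timestamp = format(Sys.time(), tz = "UTC"),
    parameters = cfg[c("fs", "highpass_hz", "notch_hz", "lowpass_hz",
                       "filter_order", "notch_q", "n_epochs", "epoch_seconds",
                       "exclude_seconds", "bins", "n_permutations", "fdr_q",
                       "swp_n_random", "seed", "surrogate_control")]
  )

  report <- structure(list(
    subjects = subjects,
    network_control = net_c, network_patient = net_p,
    network_difference = net_diff,
    density = density,
    comparisons = comparisons,
    correlations = correlations,
    connectomes = connectomes,
    masks = list(control = mask_c, patient = mask_p, difference = mask_diff,
                 union = union_mask),
    stats = list(control = stats_c, patient = stats_p,
                 difference = stats_diff),
    manifest = manifest
  ), class = "pipeline_report")

  if (!is.null(cfg$out_dir)) write_pipeline_report(report, cfg$out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat("  subjects: ", nrow(x$subjects), "\n", sep = "")
  cat("  difference network: ", nrow(x$network_difference$edges),
      " edges over ", length(x$network_difference$nodes), " nodes\n", sep = "")
  if (nrow(x$comparisons)) {
    cat("  group comparisons:\n")
    print(x$comparisons)
  }
  invisible(x)
}

#' Write a pipeline report bundle to disk
#'
#' Connectomes as headered matrix files, networks as edge-list TSVs, the
#' subject metric table, and a JSON summary holding the manifest (seed and
#' all parameters), densities, comparisons and correlations.
#'
#' @param report A `pipeline_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(report$connectomes)) {
    write_connectome(report$connectomes[[i]],
                     file.path(dir, sprintf("connectome_%s.tsv",
                                            report$subjects$subject[i])))
  }
  for (nm in c("control", "patient", "difference")) {
    net <- report[[paste0("network_", nm)]]
    write.table(net$edges, file.path(dir, paste0("network_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(report$subjects[!vapply(report$subjects, is.list, TRUE)],
              file.path(dir, "subjects.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    manifest = report$manifest,
    density = report$density,
    comparisons = report$comparisons,
    correlations = report$correlations
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
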