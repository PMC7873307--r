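# Pipeline orchestration: simulate -> fit-behavior -> encode -> decode ->
# flow -> report, as a seeded, configurable run with plain-text outputs and
# per-stage timing. Each stage consumes the previous stage's in-memory
# result; tables are written to the output directory as they are produced.

#' Pipeline configuration
#'
#' Assembles and validates the configuration of [run_pipeline()]: the seed,
#' synthetic-session overrides, the stage list, and per-stage analysis
#' settings (binning conventions, alpha, lag ranges). Unknown field names are
#' rejected with the offending name.
#'
#' @param ... Named overrides: `seed`, `session` (list of [session_config()]
#'   overrides), `stages` (character subset of simulate, fit_behavior,
#'   encode, decode, flow), `encode` (bin_width_ms, step_ms, window_s,
#'   alpha), `decode` (bin_width_ms, step_ms, window_s, domains), `flow`
#'   (self_lags, cross_lags, min_trials, domain_pairs).
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 42L,
    session = list(),
    stages = c("simulate", "fit_behavior", "encode", "decode", "flow"),
    encode = list(bin_width_ms = 50, step_ms = 10,
                  window_s = c(-1.5, 1.5), alpha = 0.05),
    decode = list(bin_width_ms = 20, step_ms = 20,
                  window_s = c(-0.5, 1.5), domains = c("action", "object")),
    flow = list(self_lags = 1:10, cross_lags = 0:10, min_trials = 30L,
                domain_pairs = NULL)
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad) || is.null(names(overrides)) ||
        any(names(overrides) == "")) {
      stop("unknown or unnamed pipeline config field(s): ",
           paste(bad, collapse = ", "))
    }
    for (nm in names(overrides)) {
      if (is.list(cfg[[nm]]) && is.list(overrides[[nm]])) {
        sub_bad <- setdiff(names(overrides[[nm]]), names(cfg[[nm]]))
        if (length(sub_bad) && nm != "session") {
          stop("unknown pipeline config field(s) in '", nm, "': ",
               paste(sub_bad, collapse = ", "))
        }
        cfg[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
      } else {
        cfg[[nm]] <- overrides[[nm]]
      }
    }
  }
  structure(cfg, class = "pipeline_config")
}

stage_log <- function(stage, t0, quiet) {
  if (!quiet) {
    message(sprintf("[lpfcflow] %-12s %6.1f s", stage,
                    as.numeric(proc.time()[3] - t0)))
  }
}

#' Run the analysis pipeline on a synthetic session
#'
#' Executes the enabled stages in dependency order: `simulate` (synthetic
#' session), `fit_behavior` (Rescorla-Wagner MLE per block type),
#' `encode` (sliding ANOVA per block type, fraction-significant courses),
#' `decode` (per-array leave-one-trial-out posteriors and accuracies per
#' domain and block type), `flow` (full/partial flow regressions and fVar
#' table). A stage whose dependency is disabled raises an error naming the
#' stage to enable. All tables are written to `out_dir` alongside a
#' `config.yaml` snapshot; the run is deterministic given `seed`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param seed Overrides `config$seed` when given.
#' @param quiet Suppress per-stage timing messages.
#' @return Invisibly, a results list: `session`, `rw_fit`, `value`,
#'   `encoding` (per block type maps + fraction table), `decoding`
#'   (posteriors, accuracy table), `flow` (summary, distance summary,
#'   example delta-posterior), `paths`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         out_dir = file.path(tempdir(), "lpfcflow_run"),
                         seed = NULL, quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) {
    stop("`config` must be built with pipeline_config()")
  }
  if (!is.null(seed)) config$seed <- seed
  stages <- config$stages
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  snap <- unclass(config)
  snap$flow$self_lags <- as.integer(snap$flow$self_lags)
  snap$flow$cross_lags <- as.integer(snap$flow$cross_lags)
  yaml::write_yaml(snap, file.path(out_dir, "config.yaml"))
  res <- list(paths = list(config = file.path(out_dir, "config.yaml")))

  need <- function(dep, stage) {
    if (!dep %in% stages) {
      stop("stage '", stage, "' requires stage '", dep,
           "'; enable '", dep, "' or disable '", stage, "'")
    }
  }

  if ("simulate" %in% stages) {
    t0 <- proc.time()[3]
    scfg <- do.call(session_config, config$session)
    res$session <- generate_session(scfg, seed = config$seed)
    p <- file.path(out_dir, "trials.csv")
    write_trial_table(res$session$trials, p)
    res$paths$trials <- p
    stage_log("simulate", t0, quiet)
  }

  if ("fit_behavior" %in% stages) {
    need("simulate", "fit_behavior")
    t0 <- proc.time()[3]
    res$rw_fit <- fit_rw_model(res$session$trials, seed = config$seed)
    res$value <- fitted_value_trace(res$rw_fit, res$session$trials)
    p <- file.path(out_dir, "rw_fit.json")
    jsonlite::write_json(
      lapply(res$rw_fit, function(f)
        c(unclass(f$params), list(nll = f$nll, converged = f$converged))),
      p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    res$paths$rw_fit <- p
    stage_log("fit_behavior", t0, quiet)
  }

  if ("encode" %in% stages) {
    need("simulate", "encode"); need("fit_behavior", "encode")
    t0 <- proc.time()[3]
    ec <- config$encode
    tensor <- bin_tensor(res$session$spikes, ec$bin_width_ms, ec$step_ms,
                         ec$window_s)
    trials <- res$session$trials
    res$encoding <- list(maps = list(), fraction = NULL)
    frac <- list()
    for (bt in unique(trials$block_type)) {
      sel <- trials$block_type == bt
      fac <- data.frame(chosen_object = trials$chosen_object[sel],
                        chosen_action = trials$chosen_action[sel],
                        reward = trials$reward[sel],
                        value = res$value[sel])
      emap <- sliding_anova(subset_tensor(tensor, trials = sel), fac,
                            alpha = ec$alpha)
      res$encoding$maps[[bt]] <- emap
      fs <- fraction_significant(emap)
      fs$block_type <- bt
      frac[[bt]] <- fs
    }
    res$encoding$fraction <- do.call(rbind, frac)
    p <- file.path(out_dir, "encoding_fraction.csv")
    utils::write.csv(res$encoding$fraction, p, row.names = FALSE)
    res$paths$encoding_fraction <- p
    stage_log("encode", t0, quiet)
  }

  if ("decode" %in% stages) {
    need("simulate", "decode")
    t0 <- proc.time()[3]
    dc <- config$decode
    tensor <- bin_tensor(res$session$spikes, dc$bin_width_ms, dc$step_ms,
                         dc$window_s)
    trials <- res$session$trials
    n_trials <- nrow(trials)
    n_bins <- length(tensor$bin_centers_s)
    posteriors <- list()
    acc_rows <- list()
    label_of <- function(domain, idx) switch(domain,
      action = trials$chosen_action[idx],
      object = trials$chosen_object[idx],
      reward = trials$reward[idx])
    for (dm in dc$domains) {
      posteriors[[dm]] <- list()
      for (aid in res$session$layout$array_id) {
        ni <- tensor$neurons$array_id == aid
        pmat <- matrix(NA_real_, n_trials, n_bins)
        for (bt in unique(trials$block_type)) {
          sel <- which(trials$block_type == bt)
          dec <- loto_decode(subset_tensor(tensor, trials = sel, neurons = ni),
                             label_of(dm, sel), domain = dm)
          pmat[sel, ] <- dec$p_true
          acc_rows[[length(acc_rows) + 1L]] <- data.frame(
            array_id = aid, domain = dm, block_type = bt,
            bin_center_s = dec$bin_centers_s, accuracy = dec$accuracy)
        }
        posteriors[[dm]][[aid]] <- pmat
      }
    }
    res$decoding <- list(posteriors = posteriors,
                         accuracy = do.call(rbind, acc_rows),
                         bin_centers_s = tensor$bin_centers_s)
    p <- file.path(out_dir, "decoding_accuracy.csv")
    utils::write.csv(res$decoding$accuracy, p, row.names = FALSE)
    res$paths$decoding_accuracy <- p
    stage_log("decode", t0, quiet)
  }

  if ("flow" %in% stages) {
    need("decode", "flow")
    t0 <- proc.time()[3]
    fl <- config$flow
    summary_df <- flow_session(
      res$decoding$posteriors, res$session$trials,
      domain_pairs = fl$domain_pairs, min_trials = fl$min_trials,
      self_lags = fl$self_lags, cross_lags = fl$cross_lags)
    dist_df <- ordinal_distance_summary(summary_df, by = "block_type")
    # one worked example: first output array, most caudal other number
    trials <- res$session$trials
    bt <- trials$block_type == trials$block_type[1]
    ids <- names(res$decoding$posteriors[[1]])
    out_id <- ids[1]
    in_list <- lapply(res$decoding$posteriors[[1]][setdiff(ids, out_id)],
                      function(m) m[bt, , drop = FALSE])
    full <- fit_flow_model(res$decoding$posteriors[[1]][[out_id]][bt, , drop = FALSE],
                           in_list, fl$self_lags, fl$cross_lags)
    dn <- max(setdiff(parse_array_number(ids), parse_array_number(out_id)))
    part <- fit_partial_model(
      res$decoding$posteriors[[1]][[out_id]][bt, , drop = FALSE], in_list, dn,
      output_id = out_id, self_lags = fl$self_lags, cross_lags = fl$cross_lags)
    res$flow <- list(summary = summary_df, by_distance = dist_df,
                     example_delta = delta_posterior(
                       full, part, res$decoding$bin_centers_s),
                     example = list(output = out_id, dropped = dn))
    p1 <- file.path(out_dir, "flow_summary.csv")
    p2 <- file.path(out_dir, "flow_by_distance.csv")
    utils::write.csv(summary_df, p1, row.names = FALSE)
    utils::write.csv(dist_df, p2, row.names = FALSE)
    res$paths$flow_summary <- p1
    res$paths$flow_by_distance <- p2
    stage_log("flow", t0, quiet)
  }

  invisible(res)
}

save_png <- function(plot, path, width = 7, height = 5) {
  grDevices::png(path, width = width, height = height, units = "in",
                 res = 120)
  on.exit(grDevices::dev.off())
  print(plot)
  invisible(path)
}

#' Render summary figures and tables from a pipeline run
#'
#' Writes the standard report figures — reversal-aligned choice curve,
#' encoding fraction-significant time courses, decoding accuracy time
#' courses, the example full-vs-partial delta-posterior trace, and mean fVar
#' by signed ordinal distance — as PNGs under `out_dir`. Figures whose stage
#' did not run are omitted with a message.
#'
#' @param results Result list from [run_pipeline()].
#' @param out_dir Directory for the figures.
#' @return Invisibly, the written figure paths.
#' @export
make_report <- function(results, out_dir = file.path(tempdir(),
                                                     "lpfcflow_report")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  skip <- function(name) message("[lpfcflow] report: stage output for '",
                                 name, "' absent; figure omitted")

  if (!is.null(results$session)) {
    curve <- reversal_aligned_choice_curve(results$session$trials)
    g <- ggplot2::ggplot(curve[!is.na(curve$mean), ],
                         ggplot2::aes(x = aligned_trial, y = mean))
    if (any(!is.na(curve$sem))) {
      g <- g + ggplot2::geom_ribbon(
        ggplot2::aes(ymin = mean - sem, ymax = mean + sem),
        alpha = 0.3, na.rm = TRUE)
    }
    g <- g +
      ggplot2::geom_line() +
      ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
      ggplot2::labs(x = "trial relative to reversal",
                    y = "fraction choosing initially better option") +
      ggplot2::ylim(0, 1)
    paths["reversal_curve"] <- save_png(
      g, file.path(out_dir, "fig_reversal_curve.png"))
  } else skip("simulate")

  if (!is.null(results$encoding)) {
    fr <- results$encoding$fraction
    g <- ggplot2::ggplot(fr, ggplot2::aes(x = bin_center_s, y = pct,
                                          colour = group)) +
      ggplot2::geom_line() +
      ggplot2::facet_grid(factor ~ block_type) +
      ggplot2::labs(x = "time from cue onset (s)",
                    y = "% significant of task-related neurons")
    paths["encoding_fraction"] <- save_png(
      g, file.path(out_dir, "fig_encoding_fraction.png"), height = 7)
  } else skip("encode")

  if (!is.null(results$decoding)) {
    ac <- results$decoding$accuracy
    g <- ggplot2::ggplot(ac, ggplot2::aes(x = bin_center_s, y = 100 * accuracy,
                                          colour = array_id)) +
      ggplot2::geom_hline(yintercept = 50, linetype = "dashed") +
      ggplot2::geom_line() +
      ggplot2::facet_grid(domain ~ block_type) +
      ggplot2::labs(x = "time from cue onset (s)", y = "decoding accuracy (%)")
    paths["decoding_accuracy"] <- save_png(
      g, file.path(out_dir, "fig_decoding_accuracy.png"), height = 6)
  } else skip("decode")

  if (!is.null(results$flow)) {
    ed <- results$flow$example_delta
    g <- ggplot2::ggplot(ed, ggplot2::aes(x = bin_center_s, y = delta)) +
      ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
      ggplot2::geom_line() +
      ggplot2::labs(
        x = "time from cue onset (s)", y = "delta posterior (full - partial)",
        title = sprintf("output %s, dropped number %d",
                        results$flow$example$output,
                        results$flow$example$dropped))
    paths["delta_posterior"] <- save_png(
      g, file.path(out_dir, "fig_delta_posterior.png"))

    bd <- results$flow$by_distance
    bd$pair <- paste(bd$in_domain, "->", bd$out_domain)
    g <- ggplot2::ggplot(bd, ggplot2::aes(x = factor(distance), y = mean_fvar,
                                          fill = block_type)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::geom_errorbar(
        ggplot2::aes(ymin = mean_fvar - sem_fvar, ymax = mean_fvar + sem_fvar),
        position = ggplot2::position_dodge(0.9), width = 0.3, na.rm = TRUE) +
      ggplot2::facet_wrap(~pair) +
      ggplot2::labs(x = "signed ordinal distance (positive = caudal to rostral)",
                    y = "fVar")
    paths["fvar_distance"] <- save_png(
      g, file.path(out_dir, "fig_fvar_distance.png"), height = 6)
  } else skip("flow")

  if (!is.null(results$learning)) {
    lt <- results$learning
    g <- ggplot2::ggplot(lt, ggplot2::aes(x = window_start, y = p)) +
      ggplot2::geom_line() +
      ggplot2::geom_hline(yintercept = 0.05, linetype = "dashed") +
      ggplot2::scale_y_log10() +
      ggplot2::labs(x = "trial-window start", y = "p (What vs Where)")
    paths["learning"] <- save_png(
      g, file.path(out_dir, "fig_learning_flow.png"))
  } else skip("learning")

  invisible(paths)
}
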