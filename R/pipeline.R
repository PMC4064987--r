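design_from_config <- function(block) {
  if (is.null(block)) return(experiment_design())
  args <- list()
  for (nm in c("n_frames", "frame_interval", "n_precontrast", "split_min")) {
    if (!is.null(block[[nm]])) args[[nm]] <- block[[nm]]
  }
  if (!is.null(block$truth_aif)) {
    args$truth_aif <- do.call(aif_params, block$truth_aif)
  }
  if (!is.null(block$truth_stage1)) {
    args$truth_stage1 <- do.call(gkm_params, block$truth_stage1)
  }
  if (!is.null(block$truth_stage2)) {
    args$truth_stage2 <- do.call(gkm_params, block$truth_stage2)
  }
  do.call(experiment_design, args)
}

noise_from_config <- function(block) {
  if (is.null(block)) return(noise_model())
  do.call(noise_model, block[names(block) %in% c("kind", "sigma", "seed")])
}

#' Run the full kinetic analysis pipeline
#'
#' Executes, per the configuration: input acquisition (read a series CSV, or
#' simulate one when a `design:` block is given and no input file), signal
#' to concentration conversion, arterial-input fitting (always on all
#' frames), then either a single kinetic fit (`mode: gkm`) or the staged
#' analysis (`mode: two_stage`). Writes a JSON report and, optionally, a
#' fitted-versus-observed plot.
#'
#' @param config An `analysis_config`, or path to a YAML configuration.
#' @return The report, invisibly: a list with blocks `input`, `aif`, and
#'   `gkm` or `two_stage`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_analysis_config(config)
  stopifnot(inherits(config, "analysis_config"))
  consts <- config$acquisition

  input_path <- config$io$input
  if (!is.null(input_path)) {
    tab <- read_series_table(input_path)
    provenance <- input_path
  } else if (!is.null(config$design)) {
    design <- design_from_config(config$design)
    noise <- noise_from_config(config$noise)
    sim <- simulate_signals(design, noise, consts)
    tab <- list(
      artery = signal_series(sim$time_min, sim$artery_signal, "artery"),
      tissue = signal_series(sim$time_min, sim$tissue_signal, "tissue"),
      dialect = "signal")
    provenance <- "simulated"
  } else {
    stop("config must provide io$input or a design block", call. = FALSE)
  }

  if (tab$dialect == "signal") {
    cp <- signal_to_concentration(tab$artery, consts)
    ct <- signal_to_concentration(tab$tissue, consts)
  } else {
    cp <- tab$artery
    ct <- tab$tissue
  }

  aif_fit <- fit_aif(cp)
  if (!isTRUE(aif_fit$converged)) {
    stop("arterial input fit failed (input: ", provenance, "): ",
         aif_fit$message, call. = FALSE)
  }

  report <- list(
    input = list(source = provenance, n_frames = nrow(cp),
                 dialect = tab$dialect),
    aif = c(unclass(aif_fit$params),
            list(rss = aif_fit$rss, converged = aif_fit$converged))
  )

  if (config$mode == "gkm") {
    fit <- fit_gkm(ct, aif_fit$params)
    if (!isTRUE(fit$converged)) {
      stop("kinetic fit failed (input: ", provenance, "): ", fit$message,
           call. = FALSE)
    }
    report$gkm <- gkm_block(fit)
    fits <- list(single = fit)
  } else {
    ts <- config$two_stage
    fit <- fit_two_stage(ct, aif_fit$params,
                         split_time = ts$split_min,
                         method = ts$smoothing,
                         n = ts$n_resample,
                         stage2_mode = ts$stage2_mode)
    report$two_stage <- list(
      split_min = fit$split_time,
      method = fit$method,
      stage2_mode = fit$stage2_mode,
      stage1 = gkm_block(fit$stage1),
      stage2 = gkm_block(fit$stage2),
      weighted_ve = fit$weighted_ve)
    fits <- list(two_stage = fit)
  }

  if (!is.null(config$io$output)) {
    jsonlite::write_json(report, config$io$output, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  if (!is.null(config$io$plot)) {
    plot_fit(ct, aif_fit$params, fits, config$io$plot)
  }
  invisible(report)
}

#' Check an analysis report against the shipped schema
#'
#' Structural validation of a report produced by [run_pipeline()] against
#' the JSON schema shipped at `inst/schema/report.schema.json`: required
#' blocks and fields present, numeric fields numeric and within bounds,
#' exactly one of the `gkm` / `two_stage` result blocks. (The check is
#' implemented directly rather than through an external JSON-Schema
#' engine; the schema file is the normative description of the report
#' format for downstream consumers.)
#'
#' @param report A report list, or path to a report JSON file.
#' @return `TRUE` invisibly; otherwise an error describing the first
#'   violation.
#' @export
validate_report <- function(report) {
  if (is.character(report)) {
    report <- jsonlite::read_json(report, simplifyVector = TRUE)
  }
  need <- function(x, fields, where) {
    missing <- setdiff(fields, names(x))
    if (length(missing)) {
      stop(sprintf("report block '%s' lacks field(s): %s", where,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  num_ok <- function(x, where, positive = FALSE) {
    if (!is.numeric(x) || !is.finite(x) || (positive && x <= 0)) {
      stop(sprintf("field '%s' must be a finite%s number", where,
                   if (positive) " positive" else ""), call. = FALSE)
    }
  }
  fit_ok <- function(x, where) {
    need(x, c("Ktrans", "Kep", "rss", "converged"), where)
    num_ok(x$Ktrans, paste0(where, "$Ktrans"))
    num_ok(x$Kep, paste0(where, "$Kep"))
    if (x$Ktrans < 0 || x$Kep < 0) {
      stop("transfer constants must be nonnegative in ", where,
           call. = FALSE)
    }
  }
  need(report, c("input", "aif"), "report")
  need(report$input, c("source", "n_frames", "dialect"), "input")
  if (!report$input$dialect %in% c("signal", "concentration")) {
    stop("input$dialect must be 'signal' or 'concentration'", call. = FALSE)
  }
  need(report$aif, c("A1", "A2", "m1", "m2", "rss", "converged"), "aif")
  num_ok(report$aif$m1, "aif$m1", positive = TRUE)
  num_ok(report$aif$m2, "aif$m2", positive = TRUE)
  has_gkm <- !is.null(report$gkm)
  has_ts <- !is.null(report$two_stage)
  if (has_gkm == has_ts) {
    stop("report must contain exactly one of 'gkm' or 'two_stage'",
         call. = FALSE)
  }
  if (has_gkm) fit_ok(report$gkm, "gkm")
  if (has_ts) {
    need(report$two_stage,
         c("split_min", "method", "stage2_mode", "stage1", "stage2",
           "weighted_ve"), "two_stage")
    fit_ok(report$two_stage$stage1, "two_stage$stage1")
    fit_ok(report$two_stage$stage2, "two_stage$stage2")
  }
  invisible(TRUE)
}

gkm_block <- function(fit) {
  list(Ktrans = fit$params$Ktrans, Kep = fit$params$Kep,
       ve = if (fit$ve_defined) fit$ve else NULL,
       rss = fit$rss, converged = fit$converged)
}

# Fitted-versus-observed tissue curve, written as PNG.
plot_fit <- function(ct, aif, fits, path) {
  grDevices::png(path, width = 900, height = 600, res = 110)
  on.exit(grDevices::dev.off(), add = TRUE)
  post <- post_contrast(ct)
  graphics::plot(post$time, post$value, pch = 16, col = "grey30",
                 xlab = "time after injection (min)",
                 ylab = "tissue Gd concentration (mM)",
                 main = "Kinetic model fit")
  tg <- seq(min(post$time), max(post$time), length.out = 400)
  if (!is.null(fits$single)) {
    graphics::lines(tg, ct_model(tg, aif, fits$single$params),
                    col = "firebrick", lwd = 2)
    graphics::legend("bottomright", legend = "single-stage fit",
                     col = "firebrick", lwd = 2, bty = "n")
  } else {
    f <- fits$two_stage
    t1 <- tg[tg <= f$split_time]
    t2 <- tg[tg >= f$split_time]
    graphics::lines(t1, ct_model(t1, aif, f$stage1$params),
                    col = "firebrick", lwd = 2)
    mu2 <- if (f$stage2_mode == "reorigin") {
      ct_model(t2 - f$split_time, aif, f$stage2$params) +
        eval_curve(f$curve, f$split_time)
    } else {
      ct_model(t2, aif, f$stage2$params) + f$stage2$offset
    }
    graphics::lines(t2, mu2, col = "dodgerblue3", lwd = 2)
    graphics::abline(v = f$split_time, lty = 3)
    graphics::legend("bottomright",
                     legend = c("stage 1 fit", "stage 2 fit"),
                     col = c("firebrick", "dodgerblue3"), lwd = 2,
                     bty = "n")
  }
}
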