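#' Read a two-compartment series table from CSV
#'
#' Two dialects are recognized by header: signal tables
#' (`time_min,artery_signal,tissue_signal`) and concentration tables
#' (`time_min,Cp_mM,Ct_mM`). Times must be strictly increasing and all
#' values finite; violations raise an error naming the offending row.
#'
#' @param path CSV file path.
#' @param dialect `"auto"` (header-based detection), `"signal"` or
#'   `"concentration"`.
#' @return A list with elements `artery` and `tissue`
#'   ([signal_series()] or [concentration_series()] according to dialect)
#'   and `dialect`.
#' @export
read_series_table <- function(path, dialect = c("auto", "signal",
                                                "concentration")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  sig_cols <- c("time_min", "artery_signal", "tissue_signal")
  conc_cols <- c("time_min", "Cp_mM", "Ct_mM")
  has <- function(cols) all(cols %in% names(df))
  if (dialect == "auto") {
    dialect <- if (has(sig_cols)) "signal"
      else if (has(conc_cols)) "concentration"
      else stop("unrecognized header in ", path,
                ": expected ", paste(sig_cols, collapse = ","),
                " or ", paste(conc_cols, collapse = ","), call. = FALSE)
  }
  cols <- if (dialect == "signal") sig_cols else conc_cols
  if (!has(cols)) {
    stop("header does not match the ", dialect, " dialect in ", path,
         call. = FALSE)
  }
  df <- df[cols]
  for (cn in cols) {
    bad <- which(!is.finite(df[[cn]]))
    if (length(bad)) {
      stop(sprintf("non-finite value in column '%s' at row %d of %s",
                   cn, bad[1L], path), call. = FALSE)
    }
  }
  nd <- which(diff(df$time_min) <= 0)
  if (length(nd)) {
    stop(sprintf("times not strictly increasing at row %d of %s",
                 nd[1L] + 1L, path), call. = FALSE)
  }
  mk <- if (dialect == "signal") signal_series else concentration_series
  list(
    artery = mk(df$time_min, df[[cols[2]]], "artery"),
    tissue = mk(df$time_min, df[[cols[3]]], "tissue"),
    dialect = dialect
  )
}

#' Write a two-compartment series table to CSV
#'
#' Inverse of [read_series_table()]: emits the signal dialect
#' (`time_min,artery_signal,tissue_signal`) for signal series and the
#' concentration dialect (`time_min,Cp_mM,Ct_mM`) for concentration series.
#'
#' @param artery,tissue Series of matching class on a common time grid.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_series_table <- function(artery, tissue, path) {
  if (!identical(class(artery), class(tissue))) {
    stop("artery and tissue series must have the same type", call. = FALSE)
  }
  if (!isTRUE(all.equal(artery$time, tissue$time))) {
    stop("artery and tissue series must share a time grid", call. = FALSE)
  }
  df <- if (inherits(artery, "signal_series")) {
    data.frame(time_min = artery$time, artery_signal = artery$value,
               tissue_signal = tissue$value)
  } else {
    data.frame(time_min = artery$time, Cp_mM = artery$value,
               Ct_mM = tissue$value)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Reduce a 4D image volume to an ROI-mean signal series
#'
#' Averages the signal over the voxels of a binary region-of-interest mask,
#' frame by frame — the mask-based generalization of averaging a fixed
#' pixel ROI across slices.
#'
#' @param images A 4D numeric array (x, y, z, frame) or path to a 4D NIfTI
#'   volume (read with the RNifti package, if installed).
#' @param mask A 3D array (nonzero = inside) or path to a 3D NIfTI mask on
#'   the same grid.
#' @param times Frame times in minutes (length = 4th dimension). If `NULL`,
#'   the default 40-frame schedule of [experiment_design()] is assumed when
#'   the frame count matches, otherwise an error is raised.
#' @param compartment Compartment label for the resulting series.
#' @return A [signal_series()] of per-frame ROI means.
#' @export
roi_mean_series <- function(images, mask, times = NULL,
                            compartment = c("tissue", "artery")) {
  compartment <- match.arg(compartment)
  images <- as_volume(images)
  mask <- as_volume(mask)
  if (length(dim(images)) != 4L) {
    stop("images must be a 4D array (x, y, z, frame)", call. = FALSE)
  }
  if (length(dim(mask)) != 3L) {
    stop("mask must be a 3D array", call. = FALSE)
  }
  if (!identical(dim(images)[1:3], dim(mask))) {
    stop("image and mask grids do not match", call. = FALSE)
  }
  if (dim(images)[4] < 3L) {
    stop("need at least 3 frames", call. = FALSE)
  }
  inside <- which(mask != 0)
  if (length(inside) == 0L) stop("mask is empty", call. = FALSE)
  n_frames <- dim(images)[4]
  flat <- matrix(images, ncol = n_frames)
  values <- colMeans(flat[inside, , drop = FALSE])
  if (is.null(times)) {
    if (n_frames == 40L) {
      times <- experiment_design()$times
    } else {
      stop("supply frame times for non-default frame counts", call. = FALSE)
    }
  }
  signal_series(times, values, compartment)
}

as_volume <- function(x) {
  if (is.character(x)) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      stop("reading NIfTI volumes requires the RNifti package",
           call. = FALSE)
    }
    x <- RNifti::readNifti(x)
  }
  arr <- as.array(x)
  storage.mode(arr) <- "double"
  arr
}

#' Read an analysis configuration from YAML
#'
#' The configuration mirrors the function arguments: an `acquisition:`
#' block (any [acquisition_constants()] field), a `two_stage:` block
#' (`split_min`, `smoothing`, `n_resample`, `stage2_mode`), optional
#' `design:`/`noise:` blocks for simulation, an `io:` block (`input`,
#' `output`, `plot`), and `mode: gkm | two_stage`.
#'
#' @param path YAML file path.
#' @return A list of class `analysis_config` with parsed component objects.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  as_analysis_config(raw)
}

#' Build an analysis configuration from a list
#'
#' @param raw Nested list with the blocks described in
#'   [read_analysis_config()].
#' @return A list of class `analysis_config`.
#' @export
as_analysis_config <- function(raw) {
  acq <- do.call(acquisition_constants,
                 as_args(raw$acquisition, formals(acquisition_constants)))
  ts_defaults <- list(split_min = 20, smoothing = "fourier5",
                      n_resample = 40L, stage2_mode = "global_offset")
  ts <- utils::modifyList(ts_defaults,
                          as_args(raw$two_stage, ts_defaults))
  mode <- raw$mode %||% "gkm"
  if (!mode %in% c("gkm", "two_stage")) {
    stop("mode must be 'gkm' or 'two_stage'", call. = FALSE)
  }
  structure(
    list(acquisition = acq, two_stage = ts, mode = mode,
         design = raw$design, noise = raw$noise,
         io = raw$io %||% list(), raw = raw),
    class = "analysis_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_args <- function(block, allowed) {
  if (is.null(block)) return(list())
  block <- block[names(block) %in% names(allowed)]
  block
}

#' Serialize an analysis configuration back to YAML
#'
#' Round-trips with [read_analysis_config()]: parsing the emitted file
#' reproduces the configuration.
#'
#' @param config An `analysis_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_analysis_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  out <- list(
    mode = config$mode,
    acquisition = config$acquisition[
      setdiff(names(config$acquisition), character(0))],
    two_stage = config$two_stage,
    design = config$design,
    noise = config$noise,
    io = config$io
  )
  out$acquisition <- unclass(out$acquisition)
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path)
  invisible(path)
}
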