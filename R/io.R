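# File I/O: numeric CSV for signals and tables, JSON sidecars for
# metadata. Dialect: comma-separated, '.' decimal, UTF-8, mandatory header
# row, NaN spelled "NaN". Signals are column-per-channel; fiducial CSVs
# have columns event_type (R/T/P) and sample_index (0-based).

meta_sidecar <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

write_meta <- function(path, meta) {
  meta$package_version <- as.character(utils::packageVersion("tvis"))
  jsonlite::write_json(meta, meta_sidecar(path), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
}

read_meta <- function(path) {
  sc <- meta_sidecar(path)
  if (file.exists(sc)) jsonlite::read_json(sc, simplifyVector = TRUE)
  else NULL
}

#' Write a multichannel signal to CSV with a JSON sidecar
#'
#' @param x Numeric matrix (one column per channel), `ts_record`, or list
#'   of `ts_record`s.
#' @param path Output CSV path; metadata goes to the `.json` sidecar.
#' @param fs Sampling rate (required for plain matrices).
#' @param meta Named list of extra metadata (seed, config, ...).
#' @return `path`, invisibly.
#' @export
write_signals <- function(x, path, fs = NULL, meta = list()) {
  if (inherits(x, "ts_record")) x <- list(x)
  if (is.list(x) && all(vapply(x, inherits, logical(1), "ts_record"))) {
    fs <- fs %||% x[[1L]]$fs
    labels <- vapply(seq_along(x), function(i) {
      lb <- x[[i]]$label
      if (nzchar(lb)) lb else sprintf("ch%02d", i)
    }, character(1))
    x <- do.call(cbind, lapply(x, `[[`, "samples"))
    colnames(x) <- labels
  }
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- sprintf("ch%02d", seq_len(ncol(x)))
  if (is.null(fs)) stop_tvis("`fs` is required", "tvis_invalid_config")
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  write_meta(path, c(list(fs = fs, n_samples = nrow(x),
                          channels = colnames(x)), meta))
  invisible(path)
}

#' Read a multichannel signal CSV (with optional JSON sidecar)
#'
#' @param path CSV path.
#' @param fs Sampling rate; overrides the sidecar value if given.
#' @return List with `data` (matrix), `fs`, `meta`.
#' @export
read_signals <- function(path, fs = NULL) {
  if (!file.exists(path))
    stop_tvis(sprintf("file not found: %s", path), "tvis_io_error")
  d <- utils::read.csv(path, check.names = FALSE)
  meta <- read_meta(path)
  fs <- fs %||% meta$fs
  if (is.null(fs))
    stop_tvis("sampling rate unknown: no sidecar and no `fs` supplied",
              "tvis_io_error")
  list(data = as.matrix(d), fs = fs, meta = meta)
}

#' Write fiducials to CSV (columns event_type, sample_index; 0-based)
#' @param fid A `"fiducial_set"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fiducials <- function(fid, path) {
  stopifnot(inherits(fid, "fiducial_set"))
  df <- rbind(
    data.frame(event_type = "R", sample_index = fid$r_idx - 1L),
    data.frame(event_type = "T", sample_index = fid$t_idx - 1L),
    data.frame(event_type = "P", sample_index = fid$p_idx - 1L))
  df <- df[order(df$sample_index), ]
  utils::write.csv(df, path, row.names = FALSE)
  write_meta(path, list(fs = fid$fs))
  invisible(path)
}

#' Read fiducials from CSV
#' @param path CSV with columns `event_type` and `sample_index` (0-based).
#' @param fs Sampling rate; overrides the sidecar value if given.
#' @return A `"fiducial_set"`.
#' @export
read_fiducials <- function(path, fs = NULL) {
  if (!file.exists(path))
    stop_tvis(sprintf("file not found: %s", path), "tvis_io_error")
  d <- utils::read.csv(path)
  fs <- fs %||% read_meta(path)$fs
  if (is.null(fs))
    stop_tvis("sampling rate unknown: no sidecar and no `fs` supplied",
              "tvis_io_error")
  pick <- function(tp) sort(d$sample_index[d$event_type == tp]) + 1L
  r <- pick("R")
  t_all <- pick("T")
  p_all <- pick("P")
  nc <- length(r) - 1L
  if (nc < 1L) stop_tvis("need at least two R events", "tvis_invalid_config")
  # assign the T in (R_k, R_{k+1}) and the P in (T_k, R_{k+1}) to cycle k
  t_idx <- p_idx <- rep(NA_integer_, nc)
  for (k in seq_len(nc)) {
    tk <- t_all[t_all > r[k] & t_all < r[k + 1L]]
    pk <- p_all[p_all > r[k] & p_all < r[k + 1L]]
    if (length(tk)) t_idx[k] <- tk[1L]
    if (length(pk)) p_idx[k] <- pk[length(pk)]
  }
  if (anyNA(t_idx) || anyNA(p_idx))
    stop_tvis("missing T or P event inside a cardiac cycle",
              "tvis_invalid_config")
  fiducial_set(R = r, T = t_idx, P = p_idx, fs = fs, units = "samples")
}

#' Serialize a TV-AR model to CSV (+ JSON metadata)
#' @param model A `"tvar_model"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tvar <- function(model, path) {
  stopifnot(inherits(model, "tvar_model"))
  a <- t(model$coeffs$values)
  colnames(a) <- sprintf("a_%d", seq_len(model$p))
  df <- data.frame(n = seq_len(nrow(a)), a, sigma2_U = model$innov_var,
                   Z = model$apriori_err, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  write_meta(path, list(p = model$p, forgetting = model$forgetting,
                        init_delta = model$init_delta, sigma0 = model$sigma0,
                        fs = model$fs, valid_from = model$valid_from))
  invisible(path)
}

#' Serialize an IS trajectory to CSV (+ JSON metadata)
#' @param traj An `"is_trajectory"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_is_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "is_trajectory"))
  df <- data.frame(n = seq_along(traj$S), S_nats = traj$S,
                   sigma2_Y = traj$proc_var, sigma2_U = traj$innov_var,
                   stable = traj$stable)
  utils::write.csv(df, path, row.names = FALSE)
  write_meta(path, list(fs = traj$fs, valid_from = traj$valid_from,
                        n_unstable = traj$n_unstable,
                        n_floored = traj$n_floored))
  invisible(path)
}
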