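## Session persistence and configuration. CSV is the primary interchange
## (inspectable and diffable): one EEG file per run with a header row of
## channel labels and one row per sample in microvolts, plus a cursor file
## (time_s, x, y, phase), a session manifest and the ground truth as JSON.

#' Default processing configuration
#'
#' @return Named list: notch frequency/Q, band-pass edges and order,
#'   causal vs zero-phase filtering, cursor displacement threshold,
#'   Hann-taper flag, fold-wise feature z-scoring flag, and seed.
#' @export
default_config <- function() {
  list(notch_freq = 50, notch_q = 35, band = c(5, 40), filter_order = 8,
       zero_phase = FALSE, cursor_threshold = 2, taper = FALSE,
       normalize = FALSE, seed = 1)
}

#' Read a processing configuration from JSON
#'
#' Unknown fields are rejected; missing fields fall back to
#' [default_config()] except the required `band`, `notch_freq` and
#' `filter_order`.
#'
#' @param path JSON file.
#' @return Validated configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  def <- default_config()
  required <- c("band", "notch_freq", "filter_order")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    stop("config is missing required field(s): ",
         paste(missing, collapse = ", "))
  }
  unknown <- setdiff(names(cfg), names(def))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  out <- utils::modifyList(def, cfg)
  if (length(out$band) != 2 || out$band[1] <= 0 || out$band[1] >= out$band[2]) {
    stop("config field 'band' must be c(low, high) with 0 < low < high")
  }
  out
}

#' Write a session to a directory
#'
#' @param session An `erd_session`.
#' @param dir Target directory (created).
#' @return Invisibly, `dir`.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "erd_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  run_files <- list()
  for (rn in names(session$runs)) {
    run <- session$runs[[rn]]
    eeg_f <- paste0("eeg_", rn, ".csv")
    cur_f <- paste0("cursor_", rn, ".csv")
    eeg_df <- as.data.frame(t(signif(run$eeg$samples, 7)))
    colnames(eeg_df) <- run$eeg$labels
    utils::write.csv(eeg_df, file.path(dir, eeg_f), row.names = FALSE)
    cur_df <- data.frame(time_s = run$cursor$time_s,
                         x = signif(run$cursor$x, 7),
                         y = signif(run$cursor$y, 7),
                         phase = run$cursor$phase)
    utils::write.csv(cur_df, file.path(dir, cur_f), row.names = FALSE)
    run_files[[rn]] <- list(eeg = eeg_f, cursor = cur_f)
  }
  manifest <- list(subject = session$subject, labels = session$labels,
                   eeg_rate = session$runs[[1]]$eeg$rate,
                   cursor_rate = session$runs[[1]]$cursor$rate,
                   units = "microvolt", runs = run_files)
  jsonlite::write_json(manifest, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(session$truth)) {
    jsonlite::write_json(session$truth, file.path(dir, "truth.json"),
                         digits = NA, pretty = TRUE)
  }
  if (!is.null(session$params)) {
    jsonlite::write_json(unclass(session$params),
                         file.path(dir, "params.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' Read a session from a directory
#'
#' @param dir Directory written by [write_session()] (or assembled by hand
#'   with the same layout).
#' @return An `erd_session`.
#' @export
read_session <- function(dir) {
  mf_path <- file.path(dir, "session.json")
  if (!file.exists(mf_path)) stop("missing session manifest: ", mf_path)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  runs <- lapply(names(mf$runs), function(rn) {
    eeg_p <- file.path(dir, mf$runs[[rn]]$eeg)
    cur_p <- file.path(dir, mf$runs[[rn]]$cursor)
    for (p in c(eeg_p, cur_p)) {
      if (!file.exists(p)) stop("missing session file: ", p)
    }
    eeg_df <- utils::read.csv(eeg_p, check.names = FALSE)
    if (!identical(colnames(eeg_df), as.character(mf$labels))) {
      stop("channel header of ", eeg_p, " does not match the manifest")
    }
    cur_df <- utils::read.csv(cur_p)
    need <- c("time_s", "x", "y", "phase")
    if (!all(need %in% colnames(cur_df))) {
      stop("cursor file ", cur_p, " must have columns ",
           paste(need, collapse = ", "))
    }
    list(eeg = eeg_recording(t(as.matrix(eeg_df)), mf$labels, mf$eeg_rate),
         cursor = cursor_trace(cur_df$time_s, cur_df$x, cur_df$y,
                               cur_df$phase, mf$cursor_rate))
  })
  names(runs) <- names(mf$runs)
  truth <- NULL
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) truth <- jsonlite::read_json(tf, simplifyVector = TRUE)
  params <- NULL
  pf <- file.path(dir, "params.json")
  if (file.exists(pf)) {
    params <- structure(jsonlite::read_json(pf, simplifyVector = TRUE),
                        class = "erd_params")
  }
  structure(list(runs = runs, truth = truth, params = params,
                 subject = mf$subject, labels = as.character(mf$labels)),
            class = "erd_session")
}

#' Save / load a trained model as JSON
#'
#' @param model An `erd_model`.
#' @param path JSON file path.
#' @return `model_save` invisibly returns `path`; `model_load` the model.
#' @export
model_save <- function(model, path) {
  stopifnot(inherits(model, "erd_model"))
  payload <- list(spec = unclass(model$spec), pars = model$pars,
                  X = model$X, y = model$y)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname model_save
#' @export
model_load <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  pl <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- structure(pl$spec, class = "classifier_spec")
  X <- if (!is.null(pl$X)) as.matrix(pl$X) else NULL
  pars <- pl$pars
  if (spec$kind == "naive_bayes") {
    pars$pos <- lapply(pars$pos, unlist)
    pars$neg <- lapply(pars$neg, unlist)
  }
  structure(list(spec = spec, pars = pars, X = X, y = pl$y),
            class = "erd_model")
}

#' Published six-subject benchmark reference table
#'
#' Per-subject cross-validated results (mean and sd of TPR and FPR over the
#' six folds, and GAP) of the seven classifiers from the published
#' six-subject cued-reaching benchmark, as printed, plus the printed
#' all-users column. Used to validate the aggregation conventions of
#' [summarize_benchmark()].
#'
#' @return List of data frames `per_user` (42 rows: 7 classifiers x 6
#'   subjects) and `all_users` (7 rows).
#' @export
reference_benchmark <- function() {
  path <- system.file("extdata", "reference_benchmark.csv",
                      package = "erdbench", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  list(per_user = df[df$subject != "AllUsers", ],
       all_users = df[df$subject == "AllUsers", ])
}
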