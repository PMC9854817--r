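cfg_stop <- function(...) {
  stop(errorCondition(sprintf(...), class = c("ramandx_config_error",
                                              "error", "condition")))
}
data_stop <- function(...) {
  stop(errorCondition(sprintf(...), class = c("ramandx_data_error",
                                              "error", "condition")))
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a spectrum set to disk
#'
#' Two plain-text dialects, both lossless (numbers are serialized with 17
#' significant digits, so write-then-read reproduces every double exactly):
#' \describe{
#'   \item{wide}{One CSV file: header row carries \code{sample_id},
#'     \code{label} and the wavenumber axis; one row per spectrum.}
#'   \item{perfile}{A directory with one two-column CSV
#'     (\code{wavenumber_cm1, intensity}) per spectrum plus a
#'     \code{manifest.csv} (\code{sample_id, label, path}).}
#' }
#'
#' @param set A \code{\link{spectrum_set}}.
#' @param path Output file (wide) or directory (perfile).
#' @param dialect \code{"wide"} or \code{"perfile"}.
#' @param include_ids Wide dialect only: include the \code{sample_id}
#'   column (drop it for the minimal label + axis layout).
#' @return \code{path}, invisibly.
#' @export
write_spectrum_set <- function(set, path, dialect = c("wide", "perfile"),
                               include_ids = TRUE) {
  stopifnot(inherits(set, "spectrum_set"))
  dialect <- match.arg(dialect)
  labs <- if (is.null(set$labels)) rep("", length(set)) else
    as.character(set$labels)
  if (dialect == "wide") {
    con <- file(path, "w")
    on.exit(close(con))
    header <- c(if (include_ids) "sample_id", "label", fmt_num(set$axis))
    writeLines(paste(header, collapse = ","), con)
    for (i in seq_len(length(set))) {
      row <- c(if (include_ids) set$sample_ids[i], labs[i],
               fmt_num(set$intensities[i, ]))
      writeLines(paste(row, collapse = ","), con)
    }
  } else {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    rel <- paste0(set$sample_ids, ".csv")
    for (i in seq_len(length(set))) {
      df <- data.frame(wavenumber_cm1 = fmt_num(set$axis),
                       intensity = fmt_num(set$intensities[i, ]))
      utils::write.csv(df, file.path(path, rel[i]), row.names = FALSE,
                       quote = FALSE)
    }
    manifest <- data.frame(sample_id = set$sample_ids, label = labs,
                           path = rel)
    utils::write.csv(manifest, file.path(path, "manifest.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a spectrum set
#'
#' Inverse of \code{\link{write_spectrum_set}}; see there for the dialects.
#' The wide dialect accepts files with or without the \code{sample_id}
#' column (identifiers are generated when absent). In the perfile dialect
#' every spectrum must share the manifest axis bit-exactly.
#'
#' @param path Wide CSV file or perfile directory.
#' @param dialect \code{"wide"} or \code{"perfile"}.
#' @return A \code{\link{spectrum_set}}.
#' @export
read_spectrum_set <- function(path, dialect = c("wide", "perfile")) {
  dialect <- match.arg(dialect)
  if (dialect == "wide") {
    if (!file.exists(path)) data_stop("no such file: %s", path)
    df <- utils::read.csv(path, check.names = FALSE,
                          colClasses = "character")
    nm <- names(df)
    has_ids <- identical(nm[1], "sample_id")
    lab_col <- if (has_ids) 2L else 1L
    if (nm[lab_col] != "label")
      data_stop("wide CSV must have a 'label' column before the axis")
    axis <- as.numeric(nm[-seq_len(lab_col)])
    if (any(is.na(axis)))
      data_stop("wide CSV header axis contains non-numeric entries")
    intens <- as.matrix(df[, -seq_len(lab_col), drop = FALSE])
    storage.mode(intens) <- "double"
    if (any(is.na(intens))) data_stop("ragged or non-numeric intensity rows")
    labs <- df[[lab_col]]
    if (all(labs == "")) labs <- NULL
    ids <- if (has_ids) df[[1]] else NULL
    spectrum_set(axis, intens, labs, ids)
  } else {
    man_path <- file.path(path, "manifest.csv")
    if (!file.exists(man_path)) data_stop("no manifest.csv in %s", path)
    man <- utils::read.csv(man_path, colClasses = "character")
    axis <- NULL
    intens <- NULL
    for (i in seq_len(nrow(man))) {
      f <- file.path(path, man$path[i])
      if (!file.exists(f))
        data_stop("spectrum file missing for sample_id '%s': %s",
                  man$sample_id[i], man$path[i])
      sp <- utils::read.csv(f)
      if (is.null(axis)) {
        axis <- sp$wavenumber_cm1
        intens <- matrix(NA_real_, nrow(man), length(axis))
      } else if (!identical(as.numeric(sp$wavenumber_cm1), as.numeric(axis)))
        data_stop("axis mismatch in sample_id '%s'", man$sample_id[i])
      if (length(sp$intensity) != length(axis))
        data_stop("ragged spectrum for sample_id '%s'", man$sample_id[i])
      intens[i, ] <- sp$intensity
    }
    labs <- man$label
    if (all(labs == "")) labs <- NULL
    spectrum_set(axis, intens, labs, man$sample_id)
  }
}

# ---- Run configuration ----------------------------------------------------

#' Default run configuration
#'
#' The full experiment configuration with every documented default: the
#' 241/463/100 generator, window-11/order-3 smoothing with lambda 1e5
#' airPLS, all four classifier families with their default grids, and the
#' stratified 0.7 split.
#'
#' @param ... Named overrides applied on top of the defaults using the same
#'   nesting as the YAML schema, e.g.
#'   \code{default_run_config(split = list(seed = 7))}.
#' @return Object of class \code{run_config}.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    generator = generator_config(),
    preprocess = preprocess_config(),
    models = list(
      families = c("knn", "rf", "svm", "cnn"),
      knn = list(k_grid = seq(1, 15, by = 2)),
      rf = list(n_trees_grid = c(100, 200, 500), depth_grid = c(5, 10, Inf)),
      svm = list(c_grid = c(0.1, 1, 10, 100), gamma_grid = 10^seq(-4, 0)),
      cnn = list(spec = list(), do_cv = TRUE, val_fraction = 0.2)),
    split = list(train_frac = 0.7, seed = 1),
    output = list(dir = NULL))
  cfg <- merge_config(cfg, list(...), path = "")
  validate_run_config(cfg)
}

merge_config <- function(base, user, path) {
  for (nm in names(user)) {
    p <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(base)) cfg_stop("unknown config field: %s", p)
    b <- base[[nm]]
    if (inherits(b, c("generator_config", "preprocess_config")))
      b <- unclass(b)
    if (is.list(b) && length(b) && !is.null(names(b)) &&
        is.list(user[[nm]]) && !is.null(names(user[[nm]])))
      base[[nm]] <- merge_config(b, user[[nm]], p)
    else
      base[[nm]] <- user[[nm]]
  }
  base
}

validate_run_config <- function(cfg) {
  wrap <- function(section, expr) {
    tryCatch(expr, error = function(e)
      cfg_stop("%s: %s", section, conditionMessage(e)))
  }
  if (!inherits(cfg$generator, "generator_config")) {
    g <- cfg$generator
    if (!is.null(g$peaks) && !all(vapply(g$peaks, inherits, TRUE, "peak_spec")))
      g$peaks <- lapply(g$peaks, function(p)
        wrap("generator.peaks", do.call(peak_spec, c(
          p[setdiff(names(p), "class_multipliers")],
          list(class_multipliers = unlist(p$class_multipliers))))))
    if (!is.null(g$n_per_class)) g$n_per_class <- unlist(g$n_per_class)
    if (!is.null(g$baseline_coeffs)) g$baseline_coeffs <- unlist(g$baseline_coeffs)
    cfg$generator <- wrap("generator", do.call(generator_config, g))
  }
  if (!inherits(cfg$preprocess, "preprocess_config"))
    cfg$preprocess <- wrap("preprocess", do.call(preprocess_config,
                                                 cfg$preprocess))
  m <- cfg$models
  if (!all(m$families %in% c("knn", "rf", "svm", "cnn")))
    cfg_stop("models.families: unknown family '%s'",
             setdiff(m$families, c("knn", "rf", "svm", "cnn"))[1])
  m$rf$depth_grid <- vapply(m$rf$depth_grid, function(d)
    if (is.character(d) && toupper(d) %in% c("INF", ".INF", "NULL")) Inf
    else as.numeric(d), numeric(1))
  for (nm in c("k_grid")) if (any(m$knn[[nm]] < 1))
    cfg_stop("models.knn.%s: values must be >= 1", nm)
  if (any(unlist(m$svm$c_grid) <= 0) || any(unlist(m$svm$gamma_grid) <= 0))
    cfg_stop("models.svm: C and gamma grids must be positive")
  unknown_cnn <- setdiff(names(m$cnn), c("spec", "do_cv", "val_fraction"))
  if (length(unknown_cnn))
    cfg_stop("models.cnn.%s: unknown field", unknown_cnn[1])
  if (length(m$cnn$spec))
    wrap("models.cnn.spec", do.call(cnn_spec, c(list(input_len = 1698),
                                                m$cnn$spec)))
  cfg$models <- m
  if (cfg$split$train_frac <= 0 || cfg$split$train_frac >= 1)
    cfg_stop("split.train_frac: must be in (0, 1)")
  structure(cfg, class = "run_config")
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration, fills every documented default,
#' validates the result and rejects unknown keys with the offending field
#' path. An empty file yields the full default configuration.
#'
#' @param path Path to the configuration file.
#' @return Object of class \code{run_config}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) cfg_stop("config file not found: %s", path)
  user <- tryCatch(yaml::read_yaml(path), error = function(e)
    cfg_stop("cannot parse config: %s", conditionMessage(e)))
  if (is.null(user)) user <- list()
  if (!is.list(user)) cfg_stop("config must be a mapping")
  cfg <- merge_config(unclass(default_run_config()), user, path = "")
  validate_run_config(cfg)
}

config_to_plain <- function(x) {
  if (inherits(x, c("run_config", "generator_config", "preprocess_config",
                    "peak_spec", "cnn_spec")))
    x <- unclass(x)
  if (is.list(x)) return(lapply(x, config_to_plain))
  if (is.numeric(x) && any(is.infinite(x))) return(ifelse(is.infinite(x), "Inf", as.character(x)))
  x
}

# Stable run identifier derived from the effective configuration.
config_hash <- function(cfg) {
  s <- as.character(jsonlite::toJSON(config_to_plain(cfg), auto_unbox = TRUE,
                                     digits = NA, null = "null"))
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

plainify <- function(x) {
  if (inherits(x, "confusion_matrix"))
    return(list(classes = rownames(x),
                counts = matrix(as.integer(x), nrow(x))))
  if (inherits(x, "cnn_spec") || inherits(x, "metrics_report") ||
      inherits(x, "cv_result") || inherits(x, "split_result"))
    x <- unclass(x)
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(x, plainify))
  x
}

write_report_bundle <- function(report, config, dir, elapsed = NA_real_,
                                stages = character(0)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(plainify(unclass(report)),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  for (fam in names(report$three_class)) {
    t3 <- report$three_class[[fam]]
    utils::write.csv(as.data.frame(unclass(t3$confusion)),
                     file.path(dir, sprintf("confusion_%s_3class.csv", fam)))
    roc <- do.call(rbind, lapply(names(t3$roc_points), function(cl)
      cbind(class = cl, t3$roc_points[[cl]])))
    utils::write.csv(roc, file.path(dir, sprintf("roc_%s_3class.csv", fam)),
                     row.names = FALSE)
  }
  for (pair in names(report$binary)) {
    for (fam in names(report$binary[[pair]]$families)) {
      b <- report$binary[[pair]]$families[[fam]]
      utils::write.csv(as.data.frame(unclass(b$confusion)),
                       file.path(dir, sprintf("confusion_%s_%s.csv", fam,
                                              pair)))
      utils::write.csv(b$roc_points,
                       file.path(dir, sprintf("roc_%s_%s.csv", fam, pair)),
                       row.names = FALSE)
    }
  }
  if (!is.null(report$history))
    utils::write.csv(report$history, file.path(dir, "history.csv"),
                     row.names = FALSE)
  yaml::write_yaml(config_to_plain(config), file.path(dir, "config.yaml"))
  writeLines(c(sprintf("seed: %d", report$meta$seed),
               sprintf("config_hash: %s", report$meta$config_hash),
               sprintf("stage: %s", stages),
               sprintf("elapsed_sec: %.1f", elapsed)),
             file.path(dir, "run.log"))
  invisible(dir)
}
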