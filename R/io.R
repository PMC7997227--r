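#' Load and validate a run configuration
#'
#' Reads a YAML configuration describing a scenario, an optional sweep and
#' output options, validates every field against its admissible range, and
#' returns a fully explicit \code{run_config} (all defaults resolved).
#' Unknown keys anywhere in the file are rejected with the offending name.
#'
#' The schema (version 1):
#' \preformatted{
#' scenario:
#'   non_diseased: {mean: 0.0, sd: 1.0, size: 2488} # standardized units
#'   diseased:     {mean: 2.99, sd: 0.75, size: 179}
#'   measurement:  {u_m: 0.046, n_u: 80}
#'   threshold: 2.26
#'   confidence: 0.95          # optional, default 0.95
#' sweep:                      # optional
#'   axis: threshold           # threshold|measurement_uncertainty|sample_size
#'   from: 1.1
#'   to: 2.5
#'   points: 101
#'   measures: [DOR]           # optional, default all eleven
#'   output: absolute          # absolute|relative|ci
#'   prevalence: 0.067         # required for axis sample_size
#' output:                     # optional
#'   table_format: csv         # csv|json
#'   plot_format: png          # png|svg
#' seed: 1                     # optional, used by `validate`
#' }
#' All scenario quantities are in standardized measurand units; values are
#' stored internally as fractions and rendered as percent only in display
#' columns.
#'
#' @param path Path to a YAML file.
#' @return An object of class \code{run_config}: list with elements
#'   \code{scenario}, \code{sweep} (a \code{\link{sweep_spec}} or
#'   \code{NULL}), \code{sweep_prevalence}, \code{table_format},
#'   \code{plot_format}, \code{seed}.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  check_keys(raw, c("scenario", "sweep", "output", "seed"), "top level")
  if (is.null(raw$scenario))
    stop("config field `scenario` is required", call. = FALSE)
  sc <- raw$scenario
  check_keys(sc, c("non_diseased", "diseased", "measurement", "threshold",
                   "confidence"), "scenario")
  pop <- function(x, what) {
    if (is.null(x))
      stop("config field `scenario.", what,
           "` is required (mean, sd, size)",
           call. = FALSE)
    check_keys(x, c("mean", "sd", "size"), paste0("scenario.", what))
    for (f in c("mean", "sd", "size"))
      if (is.null(x[[f]]))
        stop("config field `scenario.", what, ".", f, "` is required",
             call. = FALSE)
    tryCatch(population_sample(x$mean, x$sd, x$size),
             error = function(e) stop("in `scenario.", what, "`: ",
                                      conditionMessage(e), call. = FALSE))
  }
  if (is.null(sc$measurement))
    stop("config field `scenario.measurement` is required (u_m, n_u)",
         call. = FALSE)
  check_keys(sc$measurement, c("u_m", "n_u"), "scenario.measurement")
  if (is.null(sc$measurement$u_m) || is.null(sc$measurement$n_u))
    stop("`scenario.measurement` needs both u_m and n_u", call. = FALSE)
  if (is.null(sc$threshold))
    stop("config field `scenario.threshold` is required", call. = FALSE)
  s <- scenario(
    non_diseased = pop(sc$non_diseased, "non_diseased"),
    diseased = pop(sc$diseased, "diseased"),
    measurement = measurement_model(sc$measurement$u_m, sc$measurement$n_u),
    threshold = sc$threshold,
    confidence = if (is.null(sc$confidence)) 0.95 else sc$confidence)
  sweep <- NULL
  sweep_prev <- NULL
  if (!is.null(raw$sweep)) {
    sw <- raw$sweep
    check_keys(sw, c("axis", "from", "to", "points", "measures", "output",
                     "prevalence"), "sweep")
    for (f in c("axis", "from", "to", "points"))
      if (is.null(sw[[f]]))
        stop("config field `sweep.", f, "` is required", call. = FALSE)
    grid <- seq(sw$from, sw$to, length.out = sw$points)
    if (identical(sw$axis, "sample_size")) {
      grid <- unique(round(grid))
      if (is.null(sw$prevalence))
        stop("`sweep.prevalence` is required for a sample_size sweep",
             call. = FALSE)
      sweep_prev <- sw$prevalence
    }
    sweep <- sweep_spec(
      axis = sw$axis, grid = grid,
      measures = if (is.null(sw$measures)) dam_ids() else
        unlist(sw$measures),
      output = if (is.null(sw$output)) "absolute" else sw$output)
  }
  out <- raw$output
  if (!is.null(out))
    check_keys(out, c("table_format", "plot_format"), "output")
  table_format <- if (is.null(out$table_format)) "csv" else out$table_format
  plot_format <- if (is.null(out$plot_format)) "png" else out$plot_format
  if (!table_format %in% c("csv", "json"))
    stop("`output.table_format` must be csv or json", call. = FALSE)
  if (!plot_format %in% c("png", "svg"))
    stop("`output.plot_format` must be png or svg", call. = FALSE)
  structure(list(scenario = s, sweep = sweep,
                 sweep_prevalence = sweep_prev,
                 table_format = table_format, plot_format = plot_format,
                 seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed)),
            class = "run_config")
}

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra) > 0)
    stop("unknown config key", if (length(extra) > 1) "s", " in ", where,
         ": ", paste(extra, collapse = ", "),
         " (allowed: ", paste(allowed, collapse = ", "), ")",
         call. = FALSE)
  invisible(TRUE)
}

#' Write a run configuration back to YAML
#'
#' Serializes a \code{run_config} (with all defaults explicit) so that
#' \code{load_config(dump_config(cfg, path))} round-trips.
#'
#' @param cfg A \code{run_config}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
dump_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  s <- cfg$scenario
  lst <- list(
    scenario = list(
      non_diseased = list(mean = s$non_diseased$mean,
                          sd = s$non_diseased$sd,
                          size = s$non_diseased$n),
      diseased = list(mean = s$diseased$mean, sd = s$diseased$sd,
                      size = s$diseased$n),
      measurement = list(u_m = s$measurement$u_m, n_u = s$measurement$n_u),
      threshold = s$threshold,
      confidence = s$confidence),
    output = list(table_format = cfg$table_format,
                  plot_format = cfg$plot_format),
    seed = cfg$seed)
  if (!is.null(cfg$sweep)) {
    g <- cfg$sweep$grid
    lst$sweep <- list(axis = cfg$sweep$axis, from = min(g), to = max(g),
                      points = length(g),
                      measures = as.list(cfg$sweep$measures),
                      output = cfg$sweep$output)
    if (!is.null(cfg$sweep_prevalence))
      lst$sweep$prevalence <- cfg$sweep_prevalence
  }
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Write a result table to CSV or JSON
#'
#' CSV output keeps every numeric column at full precision (17 significant
#' digits) and appends a display-rounded twin (4 significant digits,
#' suffix \code{_disp}) for each; the column order and header are fixed, so
#' the byte output is deterministic for a fixed input. JSON output writes
#' one record per row at full precision. Flagged (undefined/unbounded)
#' cells survive the round trip through their \code{flag} column rather
#' than as empty strings.
#'
#' @param t A data frame (e.g. from \code{\link{calculator_tables}} or a
#'   sweep).
#' @param path Output path.
#' @param format \code{"csv"} or \code{"json"}.
#' @return \code{path}, invisibly.
#' @export
write_table <- function(t, path, format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(t))
  if (format == "json") {
    jsonlite::write_json(t, path, dataframe = "rows", digits = NA,
                         na = "string", auto_unbox = TRUE)
    return(invisible(path))
  }
  num <- vapply(t, is.numeric, logical(1))
  out <- t
  for (cn in names(t)[num]) {
    out[[cn]] <- sprintf("%.17g", t[[cn]])
    out[[paste0(cn, "_disp")]] <- sprintf("%.4g", signif(t[[cn]], 4))
  }
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     qmethod = "double", quote = TRUE)
  invisible(path)
}

#' Read back a table written by \code{write_table}
#'
#' Restores the full-precision numeric columns of a CSV written by
#' \code{\link{write_table}} (display columns are dropped).
#'
#' @param path CSV path.
#' @return Data frame with numeric columns restored.
#' @export
read_table_csv <- function(path) {
  t <- utils::read.csv(path, stringsAsFactors = FALSE)
  t <- t[, !grepl("_disp$", names(t)), drop = FALSE]
  for (cn in names(t)) {
    if (cn %in% c("measure", "flag", "axis")) next
    t[[cn]] <- as.numeric(t[[cn]])
  }
  t
}

#' Plot a sweep result
#'
#' Renders the sweep as line plots faceted by measure: the three
#' uncertainty components for \code{output = "absolute"}, the relative
#' components (percent) for \code{"relative"}, and the point estimate with
#' its confidence bounds for \code{"ci"}. Flagged cells become gaps, not
#' zeros. Axes are labelled with the swept symbol and the standardized
#' measurand units.
#'
#' @param r A \code{sweep_result}.
#' @param path Output path.
#' @param format \code{"png"} or \code{"svg"}.
#' @return \code{path}, invisibly.
#' @export
render_plot <- function(r, path, format = c("png", "svg")) {
  format <- match.arg(format)
  stopifnot(inherits(r, "sweep_result"), nrow(r) > 0)
  spec <- attr(r, "spec")
  df <- as.data.frame(r)
  df[df$flag != "ok",
     c("value", "u_meas", "u_samp", "u_c", "rel_meas", "rel_samp",
       "rel_c", "ci_lo", "ci_hi")] <- NA_real_
  xlab <- switch(spec$axis,
    threshold = "diagnostic threshold d (standardized units)",
    measurement_uncertainty =
      "standard measurement uncertainty u_m (standardized units)",
    sample_size = "total population sample size n")
  long <- switch(spec$output,
    absolute = reshape_components(df, c(combined = "u_c",
                                        measurement = "u_meas",
                                        sampling = "u_samp")),
    relative = {
      x <- reshape_components(df, c(combined = "rel_c",
                                    measurement = "rel_meas",
                                    sampling = "rel_samp"))
      x$y <- 100 * x$y
      x
    },
    ci = reshape_components(df, c(estimate = "value", lower = "ci_lo",
                                  upper = "ci_hi")))
  ylab <- switch(spec$output,
    absolute = "standard uncertainty",
    relative = "relative standard uncertainty (%)",
    ci = "measure value and confidence bounds")
  p <- ggplot2::ggplot(long, ggplot2::aes(
         x = axis_value, y = y, colour = component,
         linetype = component)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = xlab, y = ylab, colour = NULL, linetype = NULL) +
    ggplot2::theme_bw()
  dev <- if (format == "png") grDevices::png else grDevices::svg
  n_facet <- length(unique(long$measure))
  wh <- c(3.2 * min(n_facet, 3) + 1.5, 2.6 * ceiling(n_facet / 3) + 0.8)
  if (format == "png") {
    grDevices::png(path, width = wh[1], height = wh[2], units = "in",
                   res = 150)
  } else {
    grDevices::svg(path, width = wh[1], height = wh[2])
  }
  on.exit(grDevices::dev.off())
  print(p)
  invisible(path)
}

reshape_components <- function(df, cols) {
  do.call(rbind, lapply(names(cols), function(nm)
    data.frame(axis_value = df$axis_value, measure = df$measure,
               component = nm, y = df[[cols[nm]]],
               stringsAsFactors = FALSE)))
}
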