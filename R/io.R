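# Configuration loading, trajectory/report writers.  One structured config
# format (YAML or JSON, detected by extension/content) drives the CLI.

knownModels <- c("rpl30", "swi5", "glucosinolate", "chain")

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration with sections `model` (builder id
#' plus parameters), `simulation` (`t_end`, `reps`, `seed`,
#' `record_times` or `record_n`) and optional `output`.  Unknown keys and
#' invalid parameter values are rejected with messages naming the field;
#' model-specific defaults (the inferred case-study parameters) fill
#' whatever is omitted.
#'
#' @param path config file path.
#' @return A validated list with classes filled in: `$model`,
#'   `$simulation`, `$output`, plus `$system` (the built
#'   [reactionSystem()]) and `$chain` (for `model: chain`).
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else
    # keep YAML-1.1 boolean-ish scalars (n, y, yes, no, ...) as literal
    # strings: 'n' is a legitimate model key (chain length), and the
    # configs carry no boolean values
    yaml::yaml.load_file(path, handlers = list(
      "bool#no" = function(x) x, "bool#yes" = function(x) x))
  if (!is.list(cfg)) stop("config must be a mapping")
  bad <- setdiff(names(cfg), c("model", "simulation", "output", "units",
                               "schema"))
  if (length(bad)) stop("unknown top-level config keys: ",
                        paste(bad, collapse = ", "))
  if (is.null(cfg$model$id)) stop("missing required key: model.id")
  id <- match.arg(tolower(cfg$model$id), knownModels)
  pars <- cfg$model[setdiff(names(cfg$model), "id")]
  checkNum <- function(name, ok) {
    if (!is.null(pars[[name]]) && !ok(pars[[name]]))
      stop("invalid value for model.", name)
  }
  sim <- cfg$simulation
  if (is.null(sim)) sim <- list()
  badSim <- setdiff(names(sim), c("t_end", "reps", "seed", "record_times",
                                  "record_n"))
  if (length(badSim)) stop("unknown simulation keys: ",
                           paste(badSim, collapse = ", "))
  sim$seed <- as.integer(if (is.null(sim$seed)) 1L else sim$seed)
  sim$reps <- as.integer(if (is.null(sim$reps)) 1L else sim$reps)
  built <- switch(id,
    rpl30 = {
      checkNum("k", function(v) v > 0)
      checkNum("d", function(v) v > 1)
      if (!is.null(pars$y0) && !is.null(pars$s0) && pars$y0 > pars$s0)
        stop("invalid config: model.y0 exceeds model.s0")
      do.call(buildRPL30, stats::setNames(
        pars, sub("^d$", "D", names(pars))))
    },
    swi5 = do.call(buildSWI5, pars),
    glucosinolate = do.call(buildGlucosinolate, pars),
    chain = {
      if (is.null(pars$n) || is.null(pars$k))
        stop("missing required keys: model.n, model.k")
      do.call(chainSpec, pars)
    })
  if (is.null(sim$t_end))
    sim$t_end <- switch(id, rpl30 = 80, swi5 = 150, glucosinolate = 2e7,
                        chain = NULL)
  if (is.null(sim$record_times))
    sim$record_times <- if (!is.null(sim$t_end))
      seq(0, sim$t_end, length.out =
            if (is.null(sim$record_n)) 81L else sim$record_n)
  out <- list(model = c(list(id = id), pars), simulation = sim,
              output = cfg$output,
              units = if (is.null(cfg$units)) "time" else cfg$units)
  if (id == "chain") out$chain <- built else out$system <- built
  out
}

#' Write trajectories as tidy CSV
#'
#' Columns `time`, `species`, `count`, `replicate`, `seed`; ensemble means
#' add `se`.  An empty list writes a header-only file.
#'
#' @param trajs a [Trajectory-class] or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeTrajectories <- function(trajs, path) {
  if (is(trajs, "Trajectory")) trajs <- list(trajs)
  if (!length(trajs)) {
    utils::write.csv(data.frame(time = numeric(), species = character(),
                                count = numeric(), replicate = character(),
                                seed = integer()),
                     path, row.names = FALSE)
    return(invisible(path))
  }
  rows <- lapply(seq_along(trajs), function(i) {
    df <- asTidyFrame(trajs[[i]])
    if (df$replicate[1] != "mean") df$replicate <- as.character(i)
    df
  })
  haveSE <- vapply(rows, function(d) "se" %in% names(d), logical(1))
  if (any(haveSE))
    rows <- lapply(rows, function(d) {
      if (!"se" %in% names(d)) d$se <- NA_real_
      d
    })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read back a tidy trajectory CSV
#'
#' @param path CSV written by [writeTrajectories()].
#' @return data.frame in tidy form.
#' @export
readTrajectories <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write an analysis report
#'
#' Serializes a result object (calibration, ABC posterior, or a plain
#' named list of metrics) as CSV tables plus a small plain-text log
#' recording the seed and parameters.
#'
#' @param result a [CalibrationResult-class], [ABCPosterior-class] or
#'   named list.
#' @param path base path; `<path>.csv` and `<path>.log` are written.
#' @param meta named list of run metadata echoed into the log.
#' @return The CSV path, invisibly.
#' @export
writeReport <- function(result, path, meta = list()) {
  csv <- paste0(path, ".csv")
  log <- paste0(path, ".log")
  if (is(result, "CalibrationResult")) {
    utils::write.csv(result@perX1, csv, row.names = FALSE)
    body <- c(sprintf("alpha(x1) = %.6g + %.6g/x1",
                      result@coefficients["a0"], result@coefficients["a1"]),
              sprintf("beta(x1) = %.6g + %.6g*x1",
                      result@coefficients["b0"], result@coefficients["b1"]))
  } else if (is(result, "ABCPosterior")) {
    utils::write.csv(result@accepted, csv, row.names = FALSE)
    body <- c(sprintf("draws: %d, accepted: %d", nrow(result@draws),
                      nrow(result@accepted)),
              paste("best:", paste(sprintf("%s = %.6g", names(result@best),
                                           result@best), collapse = ", ")),
              sprintf("seed: %d", result@seed))
  } else {
    df <- data.frame(metric = names(result),
                     value = vapply(result, function(v)
                       paste(format(v), collapse = ";"), character(1)))
    utils::write.csv(df, csv, row.names = FALSE)
    body <- sprintf("%s: %s", df$metric, df$value)
  }
  meta <- c(list(package = paste0("StateDelaySSA ",
                                  as.character(utils::packageVersion("StateDelaySSA"))),
                 date = format(Sys.time(), "%Y-%m-%d %H:%M:%S")), meta)
  writeLines(c(sprintf("%s: %s", names(meta),
                       vapply(meta, function(v) paste(format(v), collapse = " "),
                              character(1))),
               "", body), log)
  invisible(csv)
}
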