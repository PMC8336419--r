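#' Baseline parameter set for sweeps
#'
#' The full fixed parameter set used by the numerical studies: group size
#' \code{d = 15}, multiplication factor \code{r = 8}, cost \code{c = 1},
#' redistribution \code{tau = 0.25}, aspiration \code{alpha = 1}, mutation
#' \code{delta = 0.03}, population \code{N = 100}, with threshold
#' \code{m = 4} and selection intensity \code{omega = 4} as the default
#' study point. Override any entry via \code{...}.
#'
#' @param ... Named overrides, e.g. \code{m = 10, omega = 0.5}.
#' @return Named list with entries \code{N, d, m, r, c, tau, omega, alpha,
#'   delta}.
#' @export
sweep_baseline <- function(...) {
  base <- list(N = 100, d = 15, m = 4, r = 8, c = 1, tau = 0.25,
               omega = 4, alpha = 1, delta = 0.03)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(base))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  base[names(dots)] <- dots
  base
}

#' Specify a parameter sweep
#'
#' @param vary Name of the parameter to sweep: one of \code{"omega"},
#'   \code{"m"}, \code{"d"}, \code{"r"}, \code{"c"}, \code{"alpha"}.
#' @param grid Strictly increasing, nonempty numeric vector of values for
#'   \code{vary}.
#' @param fixed Full baseline parameter list (see [sweep_baseline()]); the
#'   \code{vary} entry is ignored and must not be separately overridden.
#' @param methods Character subset of \code{c("exact", "weak", "strong",
#'   "monte_carlo")}.
#' @return An object of class \code{"sweep_spec"}.
#' @examples
#' sweep_spec("m", 1:14, sweep_baseline(omega = 0.5), methods = "weak")
#' @export
sweep_spec <- function(vary = c("omega", "m", "d", "r", "c", "alpha"),
                       grid, fixed = sweep_baseline(),
                       methods = c("exact", "weak", "strong")) {
  vary <- match.arg(vary)
  if (length(grid) == 0L || !is.numeric(grid))
    stop("grid must be a nonempty numeric vector", call. = FALSE)
  if (is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly increasing", call. = FALSE)
  if (length(methods) == 0L)
    stop("at least one method must be requested", call. = FALSE)
  methods <- match.arg(methods,
                       c("exact", "weak", "strong", "monte_carlo"),
                       several.ok = TRUE)
  needed <- c("N", "d", "m", "r", "c", "tau", "omega", "alpha", "delta")
  if (!all(needed %in% names(fixed)))
    stop("fixed must name all of: ", paste(needed, collapse = ", "),
         call. = FALSE)
  structure(list(vary = vary, grid = grid, fixed = fixed[needed],
                 methods = methods),
            class = "sweep_spec")
}

#' Run a parameter sweep
#'
#' Evaluates the requested abundance methods at every grid point. A grid
#' point whose parameters violate an invariant (e.g. a \code{d} below the
#' fixed threshold \code{m} in a group-size sweep, which must respect
#' \code{m < d}) produces rows with \code{NA} abundance and the error
#' message recorded; the run continues.
#'
#' @param spec A [sweep_spec()].
#' @param seed RNG seed, required when \code{"monte_carlo"} is among the
#'   methods; also makes the whole sweep reproducible.
#' @param sim Optional [sim_config()] template for the Monte-Carlo method
#'   (its seed is combined with the row index); defaults to 2e5-step runs.
#' @return A data frame of class \code{"sweep_result"} with columns
#'   \code{vary}, \code{value}, \code{method}, \code{X_A}, \code{favoured},
#'   \code{regime}, \code{error}; the spec is attached as an attribute.
#' @examples
#' sp <- sweep_spec("m", c(4, 9, 12), sweep_baseline(omega = 0.5),
#'                  methods = "weak")
#' run_sweep(sp)
#' @export
run_sweep <- function(spec, seed = NULL, sim = NULL) {
  stopifnot(inherits(spec, "sweep_spec"))
  if ("monte_carlo" %in% spec$methods && is.null(seed))
    stop("a seed is required for monte_carlo sweeps", call. = FALSE)
  rows <- list()
  for (g_idx in seq_along(spec$grid)) {
    par <- spec$fixed
    par[[spec$vary]] <- spec$grid[g_idx]
    row_err <- NA_character_
    gp <- ap <- NULL
    tryCatch({
      if (spec$vary == "d" && par$m >= par$d)
        stop("d-sweep requires m < d (m = ", par$m, ", d = ", par$d, ")")
      gp <- game_params(par$N, par$d, par$m, par$r, par$c, par$tau)
      ap <- aspiration_params(par$omega, par$alpha, par$delta)
    }, error = function(e) row_err <<- conditionMessage(e))
    for (meth in spec$methods) {
      x <- NA_real_; fav <- NA; reg <- NA_character_; err <- row_err
      if (is.na(err)) {
        res <- tryCatch(switch(meth,
          exact = average_abundance_exact(gp, ap),
          weak = weak_selection_abundance(gp, ap),
          strong = strong_selection_abundance(gp, ap),
          monte_carlo = {
            cfg <- if (is.null(sim))
              sim_config(n_steps = 2e5, burn_in = 2e4,
                         seed = seed + g_idx)
            else sim_config(sim$n_steps, sim$burn_in,
                            seed = seed + g_idx, initial_i = sim$initial_i)
            est <- estimate_abundance(gp, ap, cfg)
            abundance_result(est$abundance_mean, method = "monte_carlo")
          }), error = function(e) conditionMessage(e))
        if (is.character(res)) err <- res
        else {
          x <- res$value
          fav <- x > 0.5
          reg <- approximation_validity(gp, ap)$regime
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        vary = spec$vary, value = spec$grid[g_idx], method = meth,
        X_A = x, favoured = fav, regime = reg, error = err,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "spec") <- spec
  class(out) <- c("sweep_result", class(out))
  out
}

#' Summarise a series into monotone segments
#'
#' Partitions an ordered series into maximal non-decreasing /
#' non-increasing runs, treating changes smaller than \code{tolerance} as
#' flat. Used to check qualitative shapes such as "increases, then
#' decreases".
#'
#' @param series Ordered numeric vector.
#' @param tolerance Absolute change below which a step counts as flat
#'   (default 0).
#' @return Data frame with columns \code{start}, \code{end} (indices into
#'   \code{series}) and \code{direction} (\code{"up"}, \code{"down"} or
#'   \code{"flat"}).
#' @examples
#' trend_summary(c(1, 2, 3, 2, 1))  # up then down
#' @export
trend_summary <- function(series, tolerance = 0) {
  n <- length(series)
  if (n < 2L)
    return(data.frame(start = 1L, end = n, direction = "flat",
                      stringsAsFactors = FALSE))
  dd <- diff(series)
  step_dir <- ifelse(dd > tolerance, 1L, ifelse(dd < -tolerance, -1L, 0L))
  segs <- list()
  seg_start <- 1L
  cur <- step_dir[1L]
  for (s in seq_along(step_dir)[-1L]) {
    d <- step_dir[s]
    if (cur == 0L) cur <- d
    else if (d != 0L && d != cur) {        # direction conflict: close segment
      segs[[length(segs) + 1L]] <- c(seg_start, s, cur)
      seg_start <- s
      cur <- d
    }
  }
  segs[[length(segs) + 1L]] <- c(seg_start, n, cur)
  out <- do.call(rbind, segs)
  data.frame(start = out[, 1L], end = out[, 2L],
             direction = c("down", "flat", "up")[out[, 3L] + 2L],
             stringsAsFactors = FALSE)
}

#' Write a sweep result to disk
#'
#' CSV output carries a comment header naming every fixed parameter, so
#' each file is self-describing; JSON output mirrors the same content.
#'
#' @param result A [run_sweep()] result.
#' @param path Output file path.
#' @param format \code{"csv"} or \code{"json"}.
#' @return \code{path}, invisibly.
#' @export
write_sweep <- function(result, path, format = c("csv", "json")) {
  stopifnot(inherits(result, "sweep_result"))
  format <- match.arg(format)
  spec <- attr(result, "spec")
  if (format == "csv") {
    hdr <- c(
      paste0("# vary: ", spec$vary),
      paste0("# methods: ", paste(spec$methods, collapse = ",")),
      paste0("# fixed: ", paste(names(spec$fixed), unlist(spec$fixed),
                                sep = "=", collapse = " ")))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.csv(as.data.frame(result), con, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(vary = spec$vary, methods = spec$methods, fixed = spec$fixed,
           rows = as.data.frame(result)),
      path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}

#' Read a sweep configuration file
#'
#' Flat key-value YAML or JSON document mirroring [sweep_spec()]: keys
#' \code{vary}, \code{grid} (either a list of values or
#' \code{from}/\code{to}/\code{by}), \code{methods}, plus any fixed
#' parameter overrides (\code{N, d, m, r, c, tau, omega, alpha, delta}).
#'
#' @param path Path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return A [sweep_spec()].
#' @export
read_sweep_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(cfg$vary)) stop("config must name 'vary'", call. = FALSE)
  grid <- if (is.list(cfg$grid) && !is.null(cfg$grid$from))
    seq(cfg$grid$from, cfg$grid$to, by = cfg$grid$by)
  else unlist(cfg$grid)
  methods <- if (is.null(cfg$methods)) c("exact", "weak", "strong")
             else unlist(cfg$methods)
  par_names <- c("N", "d", "m", "r", "c", "tau", "omega", "alpha", "delta")
  overrides <- cfg[intersect(names(cfg), par_names)]
  if (cfg$vary %in% names(overrides))
    stop("the swept parameter '", cfg$vary,
         "' must not also be fixed in the config", call. = FALSE)
  fixed <- do.call(sweep_baseline, overrides)
  sweep_spec(cfg$vary, grid, fixed, methods)
}
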