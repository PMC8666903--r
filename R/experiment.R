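#' Run a batch of independent simulations
#'
#' Repeats [run_simulation] `n_runs` times with per-run seeds derived
#' deterministically from `base_seed` (drawn without replacement, so
#' distinct runs get distinct RNG streams) and averages the class-mass
#' traces pointwise. Each run is individually reproducible from its own
#' seed.
#'
#' @param config A [simulation_config]; its `seed` field is ignored in
#'   favour of the derived per-run seeds.
#' @param n_runs Number of independent runs (default 100).
#' @param base_seed Seed for the seed-derivation stream.
#' @return An object of class `batch_result`: list with `traces` (one
#'   `class_mass_trace` per run), `mean_trace` (data frame of per-iteration
#'   class masses averaged over runs), `config`, `n_runs`, `base_seed` and
#'   `run_seeds`.
#' @export
run_batch <- function(config, n_runs = 100L, base_seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  n_runs <- as.integer(n_runs)
  if (is.na(n_runs) || n_runs < 1L) {
    stop("`n_runs` must be at least 1", call. = FALSE)
  }
  set.seed(base_seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  space <- enumerate_languages(signal_inventory(), config$n_meanings %||% 4L)
  traces <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    cfg <- config
    cfg$seed <- run_seeds[r]
    traces[[r]] <- run_simulation(cfg, space)
  }
  mass_cols <- language_class_levels
  mean_mat <- Reduce(`+`, lapply(traces, function(tr) as.matrix(tr[mass_cols])))
  mean_mat <- mean_mat / n_runs
  mean_trace <- data.frame(iteration = traces[[1L]]$iteration, mean_mat)
  structure(
    list(traces = traces, mean_trace = mean_trace, config = config,
         n_runs = n_runs, base_seed = base_seed, run_seeds = run_seeds),
    class = "batch_result"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.batch_result <- function(x, ...) {
  cat("<batch_result> ", x$n_runs, " runs of ", x$config$n_iterations,
      " iterations (condition ", x$config$condition, ", gamma ",
      x$config$gamma, ")\n", sep = "")
  invisible(x)
}

#' First generation where combinatorial overtakes holistic
#'
#' A generation is one complete replacement of the population
#' (`n_agents` iterations); generation `g` covers iterations
#' `(g-1)*n_agents + 1` to `g*n_agents`. The crossover generation is the
#' smallest `g` such that, at the last iteration of `g`, the recorded
#' combinatorial mass strictly exceeds the holistic mass in the oldest
#' agent's posterior.
#'
#' @param trace A `class_mass_trace`.
#' @param n_agents Iterations per generation (default taken from the
#'   trace's config, else 10).
#' @return The crossover generation (integer), or `NA` if combinatorial
#'   never overtakes holistic within the trace.
#' @export
crossover_generation <- function(trace, n_agents = NULL) {
  stopifnot(is.data.frame(trace),
            all(c("iteration", "combinatorial", "holistic") %in% names(trace)))
  if (is.null(n_agents)) {
    cfg <- attr(trace, "config")
    n_agents <- if (!is.null(cfg)) cfg$n_agents else 10L
  }
  n_gen <- nrow(trace) %/% n_agents
  if (n_gen < 1L) return(NA_integer_)
  ends <- seq_len(n_gen) * n_agents
  crossed <- trace$combinatorial[ends] > trace$holistic[ends]
  if (!any(crossed)) NA_integer_ else which(crossed)[1L]
}

#' Summarise crossover times over a batch
#'
#' Computes each run's crossover generation, the median over runs (runs
#' that never cross count as `Inf`, so the median is not biased downward),
#' and the fraction of runs crossed by each generation.
#'
#' @param batch A [run_batch] result.
#' @return An object of class `crossover_summary`: list with
#'   `crossover_generation` (per run; `NA` = never), `median_generation`
#'   (may be `Inf`), `n_crossed`, `n_runs` and `fraction_crossed_by`
#'   (data frame with `generation` and `fraction`).
#' @export
summarize_crossovers <- function(batch) {
  stopifnot(inherits(batch, "batch_result"))
  gens <- vapply(batch$traces, crossover_generation, integer(1L))
  n_gen <- batch$config$n_iterations %/% batch$config$n_agents
  with_inf <- ifelse(is.na(gens), Inf, as.numeric(gens))
  frac <- vapply(seq_len(n_gen),
                 function(g) mean(with_inf <= g), numeric(1L))
  structure(
    list(crossover_generation = gens,
         median_generation = stats::median(with_inf),
         n_crossed = sum(!is.na(gens)),
         n_runs = batch$n_runs,
         fraction_crossed_by = data.frame(generation = seq_len(n_gen),
                                          fraction = frac)),
    class = "crossover_summary"
  )
}

#' @export
print.crossover_summary <- function(x, ...) {
  cat("<crossover_summary> ", x$n_crossed, "/", x$n_runs,
      " runs crossed; median crossover generation ", x$median_generation,
      "\n", sep = "")
  invisible(x)
}

#' Reshape a trace to long (tidy) format
#'
#' @param trace A `class_mass_trace`.
#' @param run Run identifier stored in the `run` column.
#' @return Data frame with columns `run`, `iteration`, `class`,
#'   `posterior_mass`.
#' @export
trace_long <- function(trace, run = 1L) {
  stopifnot(is.data.frame(trace))
  cls <- language_class_levels
  data.frame(
    run = run,
    iteration = rep(trace$iteration, times = length(cls)),
    class = factor(rep(cls, each = nrow(trace)), levels = cls),
    posterior_mass = unlist(trace[cls], use.names = FALSE)
  )
}

#' Write a class-mass trace to CSV
#'
#' Tidy long format (columns `run`, `iteration`, `class`,
#' `posterior_mass`) preceded by `#`-prefixed metadata lines recording the
#' full configuration and seed. Values are written at full precision so
#' the round-trip through [read_trace] is exact.
#'
#' @param trace A `class_mass_trace`.
#' @param path Output file path.
#' @param run Run identifier for the `run` column.
#' @return The path, invisibly.
#' @export
write_trace <- function(trace, path, run = 1L) {
  cfg <- attr(trace, "config")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(cfg)) {
    for (nm in names(cfg)) {
      writeLines(sprintf("# %s: %s", nm, paste(cfg[[nm]], collapse = " ")),
                 con)
    }
  }
  long <- trace_long(trace, run = run)
  long$posterior_mass <- sprintf("%.17g", long$posterior_mass)
  utils::write.csv(long, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a class-mass trace written by [write_trace]
#'
#' Restores the wide `class_mass_trace` and its configuration metadata.
#' Fails with an informative error if required columns are missing, and
#' warns if the four class masses do not sum to 1 at some iteration.
#'
#' @param path Path to a trace CSV.
#' @return A `class_mass_trace` with attribute `"config"` (a plain list of
#'   the recorded metadata, values as character).
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  meta_ix <- grep("^#", lines)
  meta <- list()
  for (ln in lines[meta_ix]) {
    kv <- sub("^#\\s*", "", ln)
    key <- sub(":.*$", "", kv)
    val <- sub("^[^:]*:\\s*", "", kv)
    meta[[key]] <- strsplit(val, " ", fixed = TRUE)[[1L]]
  }
  body_start <- if (length(meta_ix)) max(meta_ix) + 1L else 1L
  df <- tryCatch(
    utils::read.csv(text = lines[body_start:length(lines)],
                    stringsAsFactors = FALSE),
    error = function(e) {
      stop("malformed trace file at data starting line ", body_start, ": ",
           conditionMessage(e), call. = FALSE)
    }
  )
  required <- c("run", "iteration", "class", "posterior_mass")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("trace file ", path, " (header line ", body_start,
         ") is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  iters <- sort(unique(df$iteration))
  wide <- matrix(NA_real_, nrow = length(iters), ncol = 4L,
                 dimnames = list(NULL, language_class_levels))
  for (cls in language_class_levels) {
    sub <- df[df$class == cls, ]
    wide[match(sub$iteration, iters), cls] <- sub$posterior_mass
  }
  if (anyNA(wide)) {
    stop("trace file ", path, " does not contain all four classes at every ",
         "iteration", call. = FALSE)
  }
  sums <- rowSums(wide)
  if (any(abs(sums - 1) > 1e-6)) {
    warning("class masses do not sum to 1 at ", sum(abs(sums - 1) > 1e-6),
            " iteration(s); worst deviation ", max(abs(sums - 1)))
  }
  trace <- new_trace(wide, config = NULL)
  trace$iteration <- iters
  attr(trace, "config") <- meta
  trace
}

#' Plot mean class-mass dynamics, one panel per batch
#'
#' Reproduces the standard three-panel view of the dynamics: for each
#' batch, the mean posterior mass of the four language classes in the
#' oldest agent against iteration.
#'
#' @param batches A named list of [run_batch] results (names become panel
#'   titles; unnamed batches are labelled by condition and gamma).
#' @param file Optional output path; if supplied the figure is written
#'   there with [ggplot2::ggsave] (format from the extension, e.g. `.png`
#'   or `.pdf`).
#' @param width,height Device size in inches when `file` is given.
#' @return The ggplot object, invisibly.
#' @export
plot_panels <- function(batches, file = NULL, width = 9, height = 3.2) {
  if (inherits(batches, "batch_result")) batches <- list(batches)
  if (length(batches) < 1L) {
    stop("`batches` must contain at least one batch_result", call. = FALSE)
  }
  if (is.null(names(batches)) || any(names(batches) == "")) {
    auto <- vapply(batches, function(b) {
      sprintf("%s producer, gamma = %g", b$config$condition, b$config$gamma)
    }, character(1L))
    if (is.null(names(batches))) names(batches) <- auto
    else names(batches)[names(batches) == ""] <- auto[names(batches) == ""]
  }
  long <- do.call(rbind, lapply(names(batches), function(nm) {
    mt <- batches[[nm]]$mean_trace
    df <- trace_long(structure(mt, class = c("class_mass_trace", "data.frame")))
    df$panel <- nm
    df
  }))
  long$panel <- factor(long$panel, levels = names(batches))
  p <- ggplot2::ggplot(
    long,
    ggplot2::aes(x = iteration, y = posterior_mass, colour = class)
  ) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::facet_wrap(~panel, nrow = 1L, scales = "free_x") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "iteration",
                  y = "mean posterior mass (oldest agent)",
                  colour = "language class") +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = width, height = height)
  }
  invisible(p)
}
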