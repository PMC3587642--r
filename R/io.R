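#' Read and write time-series datasets
#'
#' Datasets are flat CSV files with a `time` column first and one column per
#' observed species, plus a sidecar JSON file (same path with extension
#' `.json`) recording the seed, noise level, per-species noise scales,
#' realized noise variances, and the generating model/parameters when known.
#' Numeric values round-trip losslessly at 17 significant digits.
#'
#' @param dataset a `ts_dataset`.
#' @param path CSV path.
#' @return `write_dataset()` returns the path invisibly; `read_dataset()`
#'   returns a `ts_dataset`.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "ts_dataset"))
  df <- data.frame(time = dataset$times, dataset$observations,
                   check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = ","), con)
  body <- apply(df, 1, function(row)
    paste(formatC(row, format = "g", digits = 17), collapse = ","))
  writeLines(body, con)

  meta <- list(seed = dataset$seed, noise_level = dataset$noise_level,
               noise_sd = as.list(dataset$noise_sd),
               realized_noise_var = as.list(dataset$realized_noise_var),
               truncated_negative = dataset$truncated_negative,
               source = dataset$source)
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

.sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' @rdname write_dataset
#' @param model optional [ode_model()]; when given, species columns are
#'   re-aligned (by header name) to the model's observed-species order.
#' @export
read_dataset <- function(path, model = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  hdr <- colnames(df)
  if (anyDuplicated(hdr)) stop("duplicate column header(s): ",
                               paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
  if (!"time" %in% hdr) stop("missing 'time' column")
  times <- df[["time"]]
  bad <- which(diff(times) <= 0)
  if (length(bad) > 0L)
    stop("time must be strictly increasing; violation at row ", bad[1] + 1L)
  species <- setdiff(hdr, "time")
  if (length(species) == 0L) stop("no species columns")
  if (!is.null(model)) {
    want <- model$state_names[model$observed]
    missing <- setdiff(want, species)
    if (length(missing) > 0L)
      stop("dataset lacks observed species column(s): ",
           paste(missing, collapse = ", "))
    species <- want
  }
  obs <- as.matrix(df[, species, drop = FALSE])

  meta_path <- .sidecar_path(path)
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path, simplifyVector = TRUE)
          else NULL
  ts_dataset(times, obs,
             noise_sd = if (!is.null(meta)) unlist(meta$noise_sd),
             noise_level = if (!is.null(meta)) meta$noise_level else NA,
             realized_noise_var = if (!is.null(meta)) unlist(meta$realized_noise_var),
             source = if (!is.null(meta)) meta$source,
             seed = if (!is.null(meta) && !is.null(meta$seed)) meta$seed else NA)
}

# ---------------------------------------------------------------------------
# run configuration

.config_defaults <- function() {
  list(model = NULL,
       bounds = NULL,
       optimizer = list(algorithm = "efa", NP = 20L, max_iter = 100L,
                        beta0 = 1, phi = 1, alpha = 0.2, MR = 0.5, CR = 0.9,
                        potential_fraction = 0.5, weak_width = 0.1,
                        fitness_threshold = NULL, seed = 1L,
                        eval_mode = "per_move"),
       data = list(path = NULL, synthesis = NULL),
       identifiability = list(gamma = 0.95),
       output_dir = ".")
}

#' Load and validate a run configuration
#'
#' Configurations are YAML (or JSON) files with sections `model`, optional
#' `bounds` overrides, `optimizer`, `data` (either a `path` or a `synthesis`
#' block with `noise_level`, `seed` and an optional `times: {from, to, n}`
#' grid), `identifiability`, and `output_dir`.  Unknown keys are rejected
#' with their key path; missing keys receive documented defaults.  Exactly
#' one of `data.path` / `data.synthesis` must be present.
#'
#' @param path YAML or JSON configuration file.
#' @return a validated `run_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  validate_config(raw)
}

#' @rdname load_config
#' @param config a raw configuration list (as parsed from YAML/JSON).
#' @export
validate_config <- function(config) {
  defaults <- .config_defaults()
  .check_keys(config, defaults, path = "")
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  if (is.null(cfg$model)) stop("configuration error: 'model' is required")
  if (!cfg$model %in% list_models())
    stop("configuration error: unknown model '", cfg$model, "'")
  has_path <- !is.null(cfg$data$path)
  has_syn <- !is.null(cfg$data$synthesis)
  if (has_path == has_syn)
    stop("configuration error: exactly one of data.path / data.synthesis required")
  g <- cfg$identifiability$gamma
  if (!is.numeric(g) || g <= 0 || g >= 1)
    stop("configuration error: identifiability.gamma must be in (0, 1)")
  if (!cfg$optimizer$algorithm %in% c("efa", "fa"))
    stop("configuration error: optimizer.algorithm must be 'efa' or 'fa'")
  class(cfg) <- "run_config"
  cfg
}

.check_keys <- function(x, ref, path) {
  extra <- setdiff(names(x), names(ref))
  if (length(extra) > 0L)
    stop("configuration error: unknown key '",
         paste0(sub("^\\.", "", paste0(path, ".", extra[1]))), "'")
  for (nm in names(x)) {
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])) && is.list(x[[nm]]))
      .check_keys(x[[nm]], ref[[nm]], paste0(path, ".", nm))
  }
}

#' @rdname load_config
#' @param file output path (YAML).
#' @export
write_config <- function(config, file) {
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}

# dataset from a config's data section (synthesis times default to the
# model's default grid)
.config_dataset <- function(cfg) {
  model <- get_model(cfg$model)
  if (!is.null(cfg$data$path)) return(read_dataset(cfg$data$path, model))
  syn <- cfg$data$synthesis
  times <- if (!is.null(syn$times))
    seq(syn$times$from, syn$times$to, length.out = syn$times$n)
  else model$default_times
  generate_dataset(model,
                   params = if (!is.null(syn$params)) unlist(syn$params),
                   times = times,
                   level = if (!is.null(syn$noise_level)) syn$noise_level else 0.25,
                   seed = if (!is.null(syn$seed)) syn$seed else cfg$optimizer$seed)
}

.config_efa <- function(cfg, model) {
  opt <- cfg$optimizer
  bounds <- model$bounds
  if (!is.null(cfg$bounds)) {
    for (nm in names(cfg$bounds))
      bounds[nm, ] <- unlist(cfg$bounds[[nm]])
  }
  efa_config(bounds = bounds, NP = opt$NP, max_iter = opt$max_iter,
             beta0 = opt$beta0, phi = opt$phi, alpha = opt$alpha,
             MR = opt$MR, CR = opt$CR,
             potential_fraction = opt$potential_fraction,
             weak_width = opt$weak_width,
             fitness_threshold = opt$fitness_threshold,
             seed = opt$seed, eval_mode = opt$eval_mode)
}

# ---------------------------------------------------------------------------
# command line

#' Command-line dispatcher
#'
#' Implements the subcommands of the shipped CLI script
#' (`system.file("cli", "fireflyde", package = "fireflyde")`):
#'
#' * `simulate --model <name> [--noise 0.25] [--seed 1] [--out data.csv]`
#' * `fit --model <name> --data data.csv [--algorithm efa] [--np 20]
#'   [--iterations 100] [--seed 1] [--out fit.json]`, or `fit --config
#'   run.yaml` driving everything (including data synthesis) from a
#'   [load_config()] file
#' * `identify --model <name> --data data.csv --params fit.json
#'   [--gamma 0.95] [--out report.json]`
#' * `select --models <name1,name2> --data data.csv [--gamma 0.95]
#'   [--out selection.json]` (candidates use their registry parameter sets)
#' * `benchmark --model <name> [--seeds 5] [--np 20] [--iterations 50]`
#'   (paired-seed hybrid-vs-plain comparison)
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status (0 on success), invisibly.
#' @export
fireflyde_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0L) stop("usage: fireflyde <simulate|fit|identify|select|benchmark> [--flags]")
    cmd <- args[1]
    opts <- .parse_flags(args[-1])
    switch(cmd,
      simulate = .cli_simulate(opts),
      fit = .cli_fit(opts),
      identify = .cli_identify(opts),
      select = .cli_select(opts),
      benchmark = .cli_benchmark(opts),
      stop("unknown subcommand '", cmd, "'"))
    0L
  }, error = function(e) {
    message("fireflyde: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

.parse_flags <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--")) stop("expected --flag, got '", args[i], "'")
    key <- substring(args[i], 3)
    if (i + 1L > length(args)) stop("missing value for --", key)
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}

.opt <- function(opts, key, default = NULL, required = FALSE) {
  v <- opts[[key]]
  if (is.null(v)) {
    if (required) stop("missing required flag --", key)
    return(default)
  }
  v
}

.cli_simulate <- function(opts) {
  model <- get_model(.opt(opts, "model", required = TRUE))
  seed <- as.integer(.opt(opts, "seed", 1L))
  ds <- generate_dataset(model,
                         level = as.numeric(.opt(opts, "noise", 0.25)),
                         seed = seed)
  out <- .opt(opts, "out", paste0(model$name, "_data.csv"))
  write_dataset(ds, out)
  cat("wrote", out, "and", .sidecar_path(out), "(seed", seed, ")\n")
}

.cli_fit <- function(opts) {
  if (!is.null(opts[["config"]])) {
    cfg <- load_config(opts[["config"]])
    model <- get_model(cfg$model)
    data <- .config_dataset(cfg)
    config <- .config_efa(cfg, model)
    alg <- cfg$optimizer$algorithm
  } else {
    model <- get_model(.opt(opts, "model", required = TRUE))
    data <- read_dataset(.opt(opts, "data", required = TRUE), model)
    config <- efa_config(bounds = model$bounds,
                         NP = as.integer(.opt(opts, "np", 20L)),
                         max_iter = as.integer(.opt(opts, "iterations", 100L)),
                         seed = as.integer(.opt(opts, "seed", 1L)))
    alg <- .opt(opts, "algorithm", "efa")
  }
  fit <- if (alg == "efa") run_efa(model, data, config)
         else if (alg == "fa") run_fa(model, data, config)
         else stop("unknown algorithm '", alg, "'")
  out <- .opt(opts, "out", "fit.json")
  jsonlite::write_json(
    list(model = model$name, algorithm = alg, seed = config$seed,
         best_params = as.list(fit$best_params),
         best_fitness = fit$best_fitness, evaluations = fit$evaluations),
    out, auto_unbox = TRUE, digits = NA)
  write_trace(fit, sub("\\.json$", "_trace.csv", out),
              every = as.integer(.opt(opts, "trace-every", 10L)))
  cat("best fitness", format(fit$best_fitness), "->", out, "\n")
}

.cli_identify <- function(opts) {
  model <- get_model(.opt(opts, "model", required = TRUE))
  data <- read_dataset(.opt(opts, "data", required = TRUE), model)
  pfile <- .opt(opts, "params", required = TRUE)
  params <- unlist(jsonlite::read_json(pfile, simplifyVector = TRUE)$best_params)
  params <- params[model$param_names]
  rep <- identify_model(params, model, data,
                        gamma = as.numeric(.opt(opts, "gamma", 0.95)))
  print(rep)
  write_report(rep, .opt(opts, "out", "report.json"))
}

.cli_select <- function(opts) {
  names_ <- strsplit(.opt(opts, "models", required = TRUE), ",")[[1]]
  models <- lapply(names_, get_model)
  data <- read_dataset(.opt(opts, "data", required = TRUE), models[[1]])
  cands <- lapply(models, function(m) list(model = m, params = m$default_params))
  names(cands) <- names_
  sel <- compare_models(cands, data,
                        gamma = as.numeric(.opt(opts, "gamma", 0.95)))
  print(sel)
  write_selection(sel, .opt(opts, "out", "selection.json"))
}

.cli_benchmark <- function(opts) {
  model <- get_model(.opt(opts, "model", required = TRUE))
  n_seeds <- as.integer(.opt(opts, "seeds", 5L))
  np <- as.integer(.opt(opts, "np", 20L))
  iters <- as.integer(.opt(opts, "iterations", 50L))
  data <- generate_dataset(model, seed = 1L)
  res <- t(vapply(seq_len(n_seeds), function(s) {
    cfg <- function(seed) efa_config(bounds = model$bounds, NP = np,
                                     max_iter = iters, seed = seed)
    c(efa = run_efa(model, data, cfg(s))$best_fitness,
      fa = run_fa(model, data, cfg(s))$best_fitness)
  }, c(efa = 0, fa = 0)))
  cat("paired seeds:", n_seeds, " NP:", np, " iterations:", iters, "\n")
  cat("median best fitness  efa:", format(stats::median(res[, "efa"])),
      " fa:", format(stats::median(res[, "fa"])), "\n")
}
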