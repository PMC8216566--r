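#' Load a model configuration file
#'
#' Reads a YAML configuration and returns validated parameter objects.
#' The file must contain exactly one of:
#' \describe{
#'   \item{`raw:`}{raw kinetic parameters, keys from [mito_params()]
#'     (`model`, `L`, `v`, `k_d`, `M`, `n`, `k_p`, `k_w`, `p_s`, `p_f`,
#'     `S`, `phi`, `alpha`).}
#'   \item{`targets:`}{dimensionless targets, keys from
#'     [params_from_targets()] (`f_s`, `N_s`, `khat_d`, `M`, `n`, `model`,
#'     `phi`, `alpha`).}
#' }
#' An optional `sim:` block carries [sim_config()] keys, and an optional
#' `sweep:` block carries [sweep_grid()] keys (`f_s_values`, `N_s_values`,
#' `phi_values`, `engine`, `objective`, `normalization`). Unknown keys are
#' rejected by name.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `params` ([mito_params()]), `sim`
#'   ([sim_config()] or `NULL`) and `sweep` ([sweep_grid()] or `NULL`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  # YAML 1.1 resolves bare n/y/no/off as booleans, which would mangle the
  # key "n" (demand sites); keep such tokens literal except true/false
  cf <- yaml::read_yaml(path, handlers = list(
    "bool#yes" = function(x) if (tolower(x) %in% c("true", "yes")) TRUE else x,
    "bool#no" = function(x) if (tolower(x) %in% c("false", "no")) FALSE else x))
  if (is.null(cf) || length(cf) == 0)
    stop("empty config: expected one of the blocks 'raw' or 'targets' ",
         "(and optional 'sim'/'sweep')")
  unknown_top <- setdiff(names(cf), c("raw", "targets", "sim", "sweep"))
  if (length(unknown_top))
    stop("unknown top-level config key(s): ", paste(unknown_top, collapse = ", "))
  has_raw <- !is.null(cf$raw); has_tgt <- !is.null(cf$targets)
  if (has_raw && has_tgt)
    stop("config has both 'raw' and 'targets' blocks; exactly one is required")
  if (!has_raw && !has_tgt)
    stop("config is missing a parameter block; supply exactly one of 'raw' or 'targets'")
  check_keys <- function(block, allowed, what) {
    unknown <- setdiff(names(block), allowed)
    if (length(unknown))
      stop(sprintf("unknown key(s) in '%s' block: %s", what,
                   paste(unknown, collapse = ", ")))
  }
  params <- if (has_raw) {
    check_keys(cf$raw, c("model", "L", "v", "k_d", "M", "n", "k_p", "k_w",
                         "p_s", "p_f", "S", "phi", "alpha"), "raw")
    do.call(mito_params, cf$raw)
  } else {
    check_keys(cf$targets, c("f_s", "N_s", "khat_d", "M", "n", "model",
                             "phi", "alpha"), "targets")
    missing <- setdiff(c("f_s", "N_s", "khat_d", "M", "n", "model"),
                       names(cf$targets))
    if (length(missing))
      stop("missing required key(s) in 'targets' block: ",
           paste(missing, collapse = ", "))
    do.call(params_from_targets, cf$targets)
  }
  sim <- NULL
  if (!is.null(cf$sim)) {
    check_keys(cf$sim, c("dt", "n_steps", "n_iter", "seed", "fixed_M",
                         "forbid_retrograde_fusion", "ss_placement",
                         "record_stride", "record_trajectory"), "sim")
    sim <- do.call(sim_config, cf$sim)
  }
  sweep <- NULL
  if (!is.null(cf$sweep)) {
    check_keys(cf$sweep, c("f_s_values", "N_s_values", "phi_values",
                           "engine", "objective", "normalization"), "sweep")
    d <- derive_params(params)
    args <- c(cf$sweep, list(khat_d = d$khat_d, n = params$n,
                             M = round(params$M), model = params$model,
                             cfg = if (is.null(sim)) sim_config() else sim))
    sweep <- do.call(sweep_grid, args)
  }
  list(params = params, sim = sim, sweep = sweep)
}

#' Write results to JSON or CSV
#'
#' Serializes result objects through a stable documented schema:
#' ensemble and mean-field results as a JSON summary (parameters echo plus
#' the health metrics and counts), tables (landscapes, tidied results) as
#' CSV with fixed column order.
#'
#' @param x A `mito_ensemble`, `meanfield_solution`, `sweep_optimum` or
#'   data frame.
#' @param path Output path.
#' @param format `"json"` or `"csv"`; default follows the file extension.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  ok <- tryCatch({
    if (format == "csv") {
      if (!is.data.frame(x)) x <- tidy(x)
      utils::write.csv(x, path, row.names = FALSE)
    } else {
      jsonlite::write_json(.serialize_result(x), path, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE, null = "null")
    }
    TRUE
  }, error = function(e)
    stop(sprintf("failed writing results to '%s': %s", path, conditionMessage(e))))
  invisible(path)
}

.serialize_result <- function(x) {
  if (is.data.frame(x)) return(x)
  if (inherits(x, "mito_ensemble")) {
    p <- x$params[!vapply(x$params, is.null, logical(1))]
    return(list(type = "ensemble", params = p,
                cfg = unclass(x$cfg),
                H_sites_mean = x$H_sites_mean, H_sites_std = x$H_sites_std,
                Hhat_avg_mean = x$Hhat_avg_mean, Hhat_last_mean = x$Hhat_last_mean,
                Hhat0_avg_mean = x$Hhat0_avg_mean, Hhat0_last_mean = x$Hhat0_last_mean,
                sigma_over_mean = x$sigma_over_mean,
                counts = as.list(x$counts), realized_fs = x$realized_fs))
  }
  if (inherits(x, "meanfield_solution")) {
    m <- health_metrics(x)
    p <- x$params[!vapply(x$params, is.null, logical(1))]
    return(list(type = "meanfield", params = p,
                x_sites = x$x_sites, H_sites = x$H_sites,
                Hhat_sites = m$Hhat_sites, Hhat_avg = m$Hhat_avg,
                Hhat_last = m$Hhat_last, rho = x$rho, S = x$S,
                M_total = x$M_total))
  }
  if (inherits(x, "sweep_optimum")) {
    return(list(type = "optimum", objective = x$objective,
                argmax_f_s = x$argmax_f_s, argmax_N_s = x$argmax_N_s,
                argmax_phi = x$argmax_phi, max_value = x$max_value,
                sem = x$sem))
  }
  stop("unsupported result type: ", paste(class(x), collapse = "/"))
}

#' Read back a JSON results file
#'
#' Inverse of the JSON path of [write_results()]; returns the parsed list.
#' @param path JSON file written by [write_results()].
#' @return A named list.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("results file not found: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Run manifest
#'
#' Records what produced a set of output files: the configuration echo,
#' package version, seed, timestamp, and an md5 content hash per output
#' file. Re-running with the same configuration and seed reproduces the
#' outputs bit-for-bit (timestamps aside).
#'
#' @param config_echo List echoed into the manifest (e.g. the parsed
#'   config).
#' @param seed The seed used.
#' @param outputs Character vector of output file paths to hash.
#' @param path Where to write the manifest JSON (`NULL` to only return it).
#' @return The manifest list, invisibly if written.
#' @export
run_manifest <- function(config_echo, seed, outputs = character(), path = NULL) {
  hashes <- if (length(outputs)) as.list(tools::md5sum(outputs)) else list()
  man <- list(package = "mitomaint",
              version = as.character(utils::packageVersion("mitomaint")),
              seed = seed, timestamp = format(Sys.time(), tz = "UTC"),
              config = config_echo, output_md5 = hashes)
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(man))
  }
  man
}
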