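#' Read a pipeline configuration from a flat key-value file
#'
#' Parses lines of the form `key = value` (blank lines and `#` comments
#' ignored) into an [run_config()]. Top-level keys mirror the `run_config()`
#' arguments (`n_participants`, `seed`, `n_boot`, `sequential`,
#' `resample_knowledgeable`, `count_omissions`, `output_dir`); design
#' parameters are prefixed `design_` (e.g. `design_n_blocks = 4`,
#' `design_isi_options_ms = 250,500,750`) and scalar trait-model parameters
#' `traits_` (e.g. `traits_probe_shift_mean_ms = 54.91`). Unknown keys are
#' rejected by name rather than ignored.
#'
#' @param path Path to the config file.
#' @return An `rtcit_run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("cannot read ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) {
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  }
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- trimws(vapply(kv, `[`, character(1), 2))
  if (anyDuplicated(keys)) {
    stop("duplicate config key: ", keys[duplicated(keys)][1], call. = FALSE)
  }

  run_keys <- c("n_participants", "seed", "n_boot", "sequential",
                "resample_knowledgeable", "count_omissions", "output_dir")
  design_keys <- setdiff(names(formals(design_spec)), "")
  trait_scalar_keys <- c("probe_shift_mean_ms", "probe_shift_sd_ms",
                         "target_shift_mean_ms", "target_shift_sd_ms",
                         "base_rt_mean_ms", "base_rt_between_sd_ms",
                         "within_sd_irrelevant_ms", "tau_ms",
                         "commission_rate_mean", "commission_logit_slope",
                         "error_prob_go")

  parse_val <- function(key, raw) {
    if (key %in% c("sequential", "resample_knowledgeable",
                   "count_omissions")) {
      return(as.logical(toupper(raw)))
    }
    if (key == "output_dir") return(raw)
    as.numeric(strsplit(raw, ",", fixed = TRUE)[[1]])
  }

  run_args <- list()
  design_args <- list()
  trait_args <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (k %in% run_keys) {
      run_args[[k]] <- parse_val(k, vals[i])
    } else if (startsWith(k, "design_") &&
                 sub("^design_", "", k) %in% design_keys) {
      design_args[[sub("^design_", "", k)]] <- parse_val(k, vals[i])
    } else if (startsWith(k, "traits_") &&
                 sub("^traits_", "", k) %in% trait_scalar_keys) {
      trait_args[[sub("^traits_", "", k)]] <- parse_val(k, vals[i])
    } else {
      stop("unknown config key: ", k, call. = FALSE)
    }
  }
  run_args$design <- do.call(design_spec, design_args)
  run_args$traits <- do.call(trait_model_config, trait_args)
  do.call(run_config, run_args)
}
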