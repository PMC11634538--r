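#' Default run configuration
#'
#' The out-of-the-box settings: an 80% match threshold for each of the three
#' algorithms, the 3-alleles-at-3-loci mixing rule, amelogenin excluded from
#' scoring, common-marker denominators, wide input layout and CSV output.
#'
#' @return Named list of settings.
#' @export
default_run_config <- function() {
  list(
    tan_threshold = 80,
    masters_q_threshold = 80,
    masters_r_threshold = 80,
    mix_allele_min = 3L,
    mix_marker_min = 3L,
    score_amelogenin = FALSE,
    penalize_missing = FALSE,
    layout = "wide",
    fmt = "csv"
  )
}

#' Resolve the run configuration
#'
#' Merges settings with precedence defaults < config file < flags, then
#' validates before any I/O happens. Unknown keys in the config file or the
#' flag list are fatal: a typo must never silently fall back to a default in
#' an authentication decision. The config file is flat YAML (a commented
#' template ships at
#' `system.file("extdata", "config_template.yaml", package = "strmatch")`).
#'
#' @param defaults Base settings (default [default_run_config()]).
#' @param file Optional path to a YAML config file.
#' @param flags Optional named list of command-line overrides.
#' @return A list of class `str_run_config`: the merged flat settings plus
#'   resolved `thresholds` ([str_thresholds()]) and `panel`
#'   ([str_panel()]) objects.
#' @examples
#' cfg <- resolve_config()
#' cfg$thresholds$tanabe_min  # 80
#' @export
resolve_config <- function(defaults = default_run_config(), file = NULL,
                           flags = list()) {
  cfg <- defaults
  if (!is.null(file)) {
    if (!file.exists(file)) {
      stop("config file not found: ", file, call. = FALSE)
    }
    from_file <- yaml::read_yaml(file)
    check_known_keys(from_file, names(defaults), paste0("config file ", file))
    cfg[names(from_file)] <- from_file
  }
  flags <- flags[!vapply(flags, is.null, logical(1))]
  check_known_keys(flags, names(defaults), "flags")
  cfg[names(flags)] <- flags
  validate_run_config(cfg)
  cfg$thresholds <- str_thresholds(
    tanabe_min = cfg$tan_threshold,
    masters_query_min = cfg$masters_q_threshold,
    masters_reference_min = cfg$masters_r_threshold,
    mix_allele_min = cfg$mix_allele_min,
    mix_marker_min = cfg$mix_marker_min)
  cfg$panel <- str_panel(include_amelogenin = isTRUE(cfg$score_amelogenin),
                         penalize_missing = isTRUE(cfg$penalize_missing))
  structure(cfg, class = "str_run_config")
}

check_known_keys <- function(x, known, where) {
  if (length(x) && (is.null(names(x)) || any(!nzchar(names(x))))) {
    stop("all settings in ", where, " must be named", call. = FALSE)
  }
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    stop("unknown configuration key(s) in ", where, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
}

validate_run_config <- function(cfg) {
  for (k in c("tan_threshold", "masters_q_threshold",
              "masters_r_threshold")) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 100) {
      stop(k, " must be a single number in [0, 100], got: ",
           deparse(v), call. = FALSE)
    }
  }
  for (k in c("mix_allele_min", "mix_marker_min")) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1) {
      stop(k, " must be a count >= 1, got: ", deparse(v), call. = FALSE)
    }
  }
  if (!cfg$layout %in% c("wide", "long")) {
    stop("layout must be 'wide' or 'long', got: ", cfg$layout,
         call. = FALSE)
  }
  if (!cfg$fmt %in% c("csv", "tsv", "xlsx")) {
    stop("fmt must be 'csv', 'tsv' or 'xlsx', got: ", cfg$fmt,
         call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.str_run_config <- function(x, ...) {
  cat("<str_run_config>\n")
  flat <- x[!names(x) %in% c("thresholds", "panel")]
  for (k in names(flat)) cat("  ", k, ": ", as.character(flat[[k]]), "\n",
                             sep = "")
  invisible(x)
}

#' Write a run manifest beside outputs
#'
#' Records, as JSON, the fully resolved configuration, the input files with
#' their MD5 checksums, and the files written -- an audit trail for
#' authentication decisions.
#'
#' @param config An `str_run_config`.
#' @param inputs Character vector of input file paths.
#' @param outputs Character vector of output file paths.
#' @param path Manifest destination (JSON).
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(config, inputs, outputs, path) {
  flat <- config[!names(config) %in% c("thresholds", "panel")]
  manifest <- list(
    tool = paste0("strmatch ",
                  as.character(utils::packageVersion("strmatch"))),
    config = flat,
    inputs = lapply(inputs, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))),
    outputs = as.list(outputs)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
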