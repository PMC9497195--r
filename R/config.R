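# YAML configuration layer and tabular writers.
#
# A config document has four optional blocks -- composition, allometry,
# physiology, run -- each a flat key-value mapping. Unknown keys are
# rejected; missing keys take the documented defaults, and the resolved
# config can be echoed back to file for provenance.

#' Default model configuration
#'
#' @return Nested list with blocks `composition`, `allometry`,
#'   `physiology` and `run`, holding every documented key at its
#'   default value. `physiology$fcn_fix = NULL` means "use the
#'   calibrated fixation cost" (see [calibrate_fixation_cost()]); it is
#'   resolved to a number by [load_config()].
#' @export
default_config <- function() {
  list(
    composition = list(
      n_trichomes = 2, vegetative_per_trichome = 4,
      heterocysts_per_trichome = 1, volume_diatom = 3493.5,
      volume_vegetative = 18.8, volume_heterocyst = 61.0
    ),
    allometry = default_allometry(),
    physiology = list(
      E_diatom = 0.38, E_vegetative = 0.38, E_heterocyst = 0.38,
      fcn_fix = NULL, vmax_nh4 = 1.16, km_nh4 = 0.483, rCN = 6.6,
      pmax_per_n = 20, alpha_light = 0.3,
      pmax_factor_vegetative = 1
    ),
    run = list(
      mu = 0.51, nh4 = 0, irradiance = NULL, variant = "none"
    )
  )
}

merge_block <- function(user, defaults, block) {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) {
    stop("config block '", block, "' must be a mapping", call. = FALSE)
  }
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown config key", if (length(unknown) > 1) "s", " in '",
         block, "': ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  # single-bracket assignment keeps explicit-NULL values (e.g. an
  # unset irradiance) instead of deleting the key
  for (k in names(user)) defaults[k] <- user[k]
  defaults
}

#' Load and validate a model configuration
#'
#' Reads a YAML document (from a file path or inline text), rejects
#' unknown keys, fills missing keys from [default_config()], resolves
#' the calibrated fixation cost if `fcn_fix` is unset, and validates
#' every constraint by constructing the corresponding model objects.
#' Validation errors name the offending key.
#'
#' @param path Path to a YAML config file, or `NULL`.
#' @param text Inline YAML text, used when `path` is `NULL`. `NULL` or
#'   empty text yields the full default configuration.
#' @return An object of class `dda_config`: the resolved nested list.
#' @examples
#' cfg <- load_config(text = "physiology:\n  vmax_nh4: 2.32\n")
#' cfg$physiology$vmax_nh4
#' @export
load_config <- function(path = NULL, text = NULL) {
  user <- if (!is.null(path)) {
    yaml::read_yaml(path)
  } else if (!is.null(text) && nzchar(trimws(text))) {
    yaml::yaml.load(text)
  } else {
    list()
  }
  if (is.null(user)) user <- list()
  if (!is.list(user)) stop("config must be a YAML mapping",
                           call. = FALSE)
  defaults <- default_config()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown config block", if (length(unknown) > 1) "s", ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  cfg <- list(
    composition = merge_block(user$composition, defaults$composition,
                              "composition"),
    allometry = local({
      al <- defaults$allometry
      if (!is.null(user$allometry)) {
        unknown <- setdiff(names(user$allometry), names(al))
        if (length(unknown)) {
          stop("unknown config key in 'allometry': ",
               paste(unknown, collapse = ", "), call. = FALSE)
        }
        for (cl in names(user$allometry)) {
          al[[cl]] <- merge_block(user$allometry[[cl]], al[[cl]],
                                  paste0("allometry.", cl))
        }
      }
      al
    }),
    physiology = merge_block(user$physiology, defaults$physiology,
                             "physiology"),
    run = merge_block(user$run, defaults$run, "run")
  )

  # validate by constructing the model objects; their errors already
  # name the offending key
  comp <- do.call(dda_composition, cfg$composition)
  validate_allometry(cfg$allometry)
  params <- do.call(dda_physiology, cfg$physiology)
  cfg$physiology$fcn_fix <- params$fcn_fix
  if (!is.null(cfg$run$mu)) check_positive(cfg$run$mu, "mu")
  if (!is.null(cfg$run$nh4) && cfg$run$nh4 < 0) {
    stop("nh4 must be >= 0, got ", cfg$run$nh4, call. = FALSE)
  }
  if (!cfg$run$variant %in% dda_variants()) {
    stop("unknown variant '", cfg$run$variant, "'; must be one of: ",
         paste(dda_variants(), collapse = ", "), call. = FALSE)
  }
  structure(cfg, class = "dda_config")
}

#' Write a resolved configuration back to YAML
#'
#' The echoed file reloads to an identical configuration, providing a
#' provenance record of the exact parameter values (including the
#' resolved fixation cost) used for a run.
#'
#' @param config A `dda_config` from [load_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
echo_config <- function(config, path) {
  stopifnot(inherits(config, "dda_config"))
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' Build a scenario from a resolved configuration
#'
#' @param config A `dda_config`.
#' @param warn_mu Passed through to [dda_scenario()].
#' @return A [dda_scenario()].
#' @export
config_to_scenario <- function(config, warn_mu = TRUE) {
  stopifnot(inherits(config, "dda_config"))
  dda_scenario(
    mu = config$run$mu, nh4 = config$run$nh4,
    irradiance = config$run$irradiance,
    composition = do.call(dda_composition, config$composition),
    params = do.call(dda_physiology, config$physiology),
    coeffs = config$allometry,
    variant = config$run$variant, warn_mu = warn_mu
  )
}

#' Write records to CSV or JSON
#'
#' CSV output carries a header, deterministic column order and numbers
#' rounded to 6 significant digits; JSON output is an array of flat
#' objects at full double precision. Identical records always produce
#' byte-identical files.
#'
#' @param records A data.frame of homogeneous records.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(records))
  if (format == "csv") {
    out <- records
    for (j in seq_along(out)) {
      if (is.numeric(out[[j]])) out[[j]] <- signif(out[[j]], 6)
    }
    utils::write.csv(out, path, row.names = FALSE)
  } else {
    jsonlite::write_json(records, path, dataframe = "rows",
                         digits = NA, na = "null", auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read records written by [write_records()]
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`.
#' @return data.frame of records.
#' @export
read_records <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  }
}
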