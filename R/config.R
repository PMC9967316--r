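#' Analysis configuration
#'
#' Default knobs of the synergy pipeline, optionally overridden from a YAML
#' file. Recognized fields: `bootstrap` (resamples B), `conf_level`,
#' `alpha` (escalation / constancy threshold), `effect_level` (`"auto"` for
#' the two-stage escalation rule, or a fixed number), `combo_dose_a`,
#' `combo_dose_b` (µM), and `blank_subtraction` (logical; subtract a blank
#' before normalization - off by default).
#'
#' @param path Optional path to a YAML file; fields present there override
#'   the defaults. Unknown fields are an error.
#' @return A named list of configuration values.
#' @export
synergy_config <- function(path = NULL) {
  defaults <- list(bootstrap = 2000, conf_level = 0.95, alpha = 0.05,
                   effect_level = "auto", combo_dose_a = 10,
                   combo_dose_b = 20, blank_subtraction = FALSE)
  if (is.null(path)) return(defaults)
  if (!file.exists(path)) abort(sprintf("config file '%s' does not exist.", path))
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    abort(sprintf("unknown config field(s): %s.", paste(unknown, collapse = ", ")))
  }
  modifyList(defaults, user)
}
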