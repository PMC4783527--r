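# Condition classes shared by all modules.  Every user-facing failure is a
# classed condition so the CLI can map it to a stable exit code:
#   svz_usage_error      -> 1
#   svz_format_error     -> 2   (unparsable input file)
#   svz_validation_error -> 3   (annotation/collinearity disagree)
#   svz_render_error     -> 4   (output stage)
# svz_config_error and svz_layout_error are treated as usage errors.

svz_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "svz_error")))
}

svz_format_error     <- function(msg) svz_stop(msg, "svz_format_error")
svz_config_error     <- function(msg) svz_stop(msg, "svz_config_error")
svz_validation_error <- function(msg) svz_stop(msg, "svz_validation_error")
svz_layout_error     <- function(msg) svz_stop(msg, "svz_layout_error")
svz_render_error     <- function(msg) svz_stop(msg, "svz_render_error")
svz_usage_error      <- function(msg) svz_stop(msg, "svz_usage_error")
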