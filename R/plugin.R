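# deterministic content hash (32-bit FNV-1a) used for task ids and result
# file checksums; no cryptographic strength intended
.content_hash <- function(text) {
  bytes <- utf8ToInt(paste(text, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    # xor emulated on 16-bit halves to stay in exact double arithmetic
    lo <- bitwXor(h %% 65536, b)
    h <- (h - h %% 65536) + lo
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Define a model plug-in
#'
#' The simulation manager is model-agnostic: a model takes part only
#' through its full input-parameter listing and an entry point mapping a
#' complete parameter assignment plus a protocol to a time-series result.
#' The entry point must be self-contained — its behaviour depends only on
#' its inputs — so that a task document fully defines a simulation.
#'
#' @param model_id short identifier.
#' @param parameters [mdsp_parameters()]-like listing (values + meta).
#' @param entry `function(assignment, protocol, output_spec)` returning a
#'   data.frame with a `time` column.
#' @return object of class `model_plugin`.
#' @export
model_plugin <- function(model_id, parameters, entry) {
  stopifnot(is.character(model_id), is.function(entry),
            !is.null(parameters$values), !is.null(parameters$meta))
  structure(list(model_id = model_id, parameters = parameters,
                 entry = entry), class = "model_plugin")
}

#' The metabolic-model plug-in
#'
#' Wraps [simulate_protocol()] behind the plug-in contract: the assignment
#' must cover every model parameter; drugs referenced by the protocol's
#' regimens resolve from `drugs`.
#'
#' @param drugs named list of [drug_parameters()].
#' @param hypotheses hypothesis switches ([default_hypotheses()]).
#' @return [model_plugin()].
#' @export
mdsp_plugin <- function(drugs = builtin_drugs(),
                        hypotheses = default_hypotheses()) {
  template <- mdsp_parameters()
  entry <- function(assignment, protocol, output_spec = NULL) {
    missing <- setdiff(names(template$values), names(assignment))
    if (length(missing))
      stop("incomplete parameter assignment; missing: ",
           paste(missing, collapse = ", "), call. = FALSE)
    p <- template
    p$values[names(template$values)] <- assignment[names(template$values)]
    if (!is.null(output_spec)) {
      if (!is.null(output_spec$outputs)) protocol$outputs <- output_spec$outputs
      if (!is.null(output_spec$interval))
        protocol$output_interval <- output_spec$interval
    }
    simulate_protocol(p, protocol, drugs = drugs, hypotheses = hypotheses)
  }
  model_plugin("mdsp", template, entry)
}

#' Keyword filter over a plug-in's parameter listing
#'
#' @param plugin [model_plugin()].
#' @param keyword substring matched against parameter names (fixed, not
#'   regex).
#' @return character vector of matching parameter names.
#' @export
filter_parameters <- function(plugin, keyword) {
  nm <- names(plugin$parameters$values)
  nm[grepl(keyword, nm, fixed = TRUE)]
}
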