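#' Exposed-parameter UI schema
#'
#' The configurable surface of a model: which parameters are shown, with
#' what label and control, where in the section grid, and under which unit
#' category.  Desk-scale stand-in for a configurable web UI.
#'
#' @param controls data.frame with columns `section`, `parameter`, `label`,
#'   `control` (`checkbox`/`text`/`dropdown`), `category`, `row`, `column`.
#' @return object of class `exposed_schema`.
#' @export
exposed_schema <- function(controls) {
  need <- c("section", "parameter", "label", "control", "category", "row",
            "column")
  missing <- setdiff(need, names(controls))
  if (length(missing))
    stop("schema is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(controls$control), c("checkbox", "text", "dropdown"))
  if (length(bad))
    stop("unknown control kind(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(controls = controls), class = "exposed_schema")
}

#' Validate a UI schema against a model plug-in
#'
#' Flags parameters the plug-in does not know, duplicate grid cells
#' (section, row, column), and category mismatches against the listing's
#' metadata.  Report-based: an empty report means the schema is valid.
#'
#' @param schema [exposed_schema()].
#' @param plugin [model_plugin()].
#' @return list with `unknown_parameters`, `duplicate_cells`,
#'   `category_mismatches` (character vectors) and `valid` (logical).
#' @export
validate_schema <- function(schema, plugin) {
  ctl <- schema$controls
  known <- names(plugin$parameters$values)
  unknown <- setdiff(ctl$parameter, known)
  cell <- paste(ctl$section, ctl$row, ctl$column, sep = "/")
  dup <- unique(cell[duplicated(cell)])
  meta <- plugin$parameters$meta
  model_cat <- meta$category[match(ctl$parameter, meta$name)]
  mism <- ctl$parameter[!is.na(model_cat) & model_cat != ctl$category]
  list(unknown_parameters = unknown, duplicate_cells = dup,
       category_mismatches = unique(mism),
       valid = !length(unknown) && !length(dup) && !length(mism))
}

.unit_registry <- list(
  DOSE   = c(ug = 1e-3, mg = 1, g = 1e3),
  TIME   = c(min = 1 / 60, h = 1, day = 24),
  VOLUME = c(mL = 1e-3, L = 1)
)

#' Exact unit conversion within a category
#'
#' @param value numeric value(s).
#' @param category unit category (`"DOSE"`, `"TIME"`, `"VOLUME"`).
#' @param from,to unit names registered for the category.
#' @return converted value; round trips are exact.
#' @export
convert_units <- function(value, category, from, to) {
  reg <- .unit_registry[[category]]
  if (is.null(reg))
    stop("no unit registry for category: ", category, call. = FALSE)
  if (!from %in% names(reg) || !to %in% names(reg))
    stop(sprintf("unknown unit pair %s -> %s for category %s", from, to,
                 category), call. = FALSE)
  value * reg[[from]] / reg[[to]]
}
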