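#' Create a virtual patient
#'
#' A virtual patient is a named, phenotype-tagged parameter assignment: the
#' base model listing plus a (possibly empty) set of overrides.
#'
#' @param base [mdsp_parameters()] the overrides are validated against.
#' @param overrides named list/vector of parameter values.
#' @param phenotypes character vector of phenotype tags (non-empty), e.g.
#'   `c("t2dm", "obese")`.
#' @param id short identifier; defaults to a name derived from phenotypes.
#' @param name display name.
#' @param note free-text provenance note.
#' @return object of class `virtual_patient`.
#' @export
make_vp <- function(base, overrides = list(), phenotypes, id = NULL,
                    name = NULL, note = "") {
  stopifnot(inherits(base, "mdsp_parameters"))
  if (missing(phenotypes) || !length(phenotypes))
    stop("phenotype tags must be non-empty", call. = FALSE)
  ov <- unlist(overrides)
  unknown <- setdiff(names(ov), names(base$values))
  if (length(unknown))
    stop("unknown parameter name(s) in overrides: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  id <- id %||% paste(phenotypes, collapse = "_")
  structure(list(id = id, name = name %||% id,
                 phenotypes = as.character(phenotypes),
                 overrides = as.list(ov), note = note),
            class = "virtual_patient")
}

#' @export
print.virtual_patient <- function(x, ...) {
  cat(sprintf("<virtual_patient> %s [%s] (%d override%s)\n", x$id,
              paste(x$phenotypes, collapse = ", "), length(x$overrides),
              if (length(x$overrides) == 1) "" else "s"))
  invisible(x)
}

#' Resolve a virtual patient to a full parameter assignment
#'
#' @param vp [make_vp()].
#' @param base [mdsp_parameters()].
#' @return [mdsp_parameters()] with the overrides applied.  Resolution is
#'   idempotent: resolving an already resolved set changes nothing.
#' @export
resolve_vp <- function(vp, base = mdsp_parameters()) {
  stopifnot(inherits(vp, "virtual_patient"))
  set_parameters(base, vp$overrides)
}

#' Select virtual patients by phenotype
#'
#' @param store list of virtual patients.
#' @param phenotypes tags to match.
#' @param and_logic `TRUE`: a patient must carry all requested tags;
#'   `FALSE`: any tag suffices.
#' @return sub-list in store order (possibly empty).
#' @export
select_vps <- function(store, phenotypes, and_logic = FALSE) {
  hit <- vapply(store, function(vp) {
    if (and_logic) all(phenotypes %in% vp$phenotypes)
    else any(phenotypes %in% vp$phenotypes)
  }, TRUE)
  store[hit]
}

#' Enrollment-range check on a virtual patient
#'
#' Validates that the patient's fasting steady-state glucose lies within a
#' study's enrollment window (default 7-12 mM, the typical inclusion
#' criterion of short-term metformin studies in T2DM).
#'
#' @param vp [make_vp()].
#' @param base [mdsp_parameters()].
#' @param fpg_range length-2 numeric, inclusive bounds (mM).
#' @return logical, with attribute `FPG`.
#' @export
vp_meets_enrollment <- function(vp, base = mdsp_parameters(),
                                fpg_range = c(7, 12)) {
  ss <- steady_state(resolve_vp(vp, base))
  fpg <- ss[["G_plasma"]]
  structure(fpg >= fpg_range[1] && fpg <= fpg_range[2], FPG = fpg)
}

#' Write / read a virtual patient as structured text
#'
#' One human-readable file per patient: header keys (`id`, `name`,
#' `phenotypes`, `note`) followed by one `override: name<TAB>value` line per
#' override.  Values round-trip bit-exactly.
#'
#' @param vp [make_vp()].
#' @param path file path.
#' @return `write_vp` the path invisibly; `read_vp` a `virtual_patient`.
#' @export
write_vp <- function(vp, path) {
  lines <- c(
    paste0("id: ", vp$id),
    paste0("name: ", vp$name),
    paste0("phenotypes: ", paste(vp$phenotypes, collapse = ", ")),
    paste0("note: ", vp$note),
    vapply(names(vp$overrides), function(nm)
      sprintf("override: %s\t%s", nm,
              format(vp$overrides[[nm]], digits = 17, trim = TRUE,
                     scientific = FALSE)), ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_vp
#' @param base [mdsp_parameters()] used to validate override names.
#' @export
read_vp <- function(path, base = mdsp_parameters()) {
  lines <- readLines(path)
  get1 <- function(key) {
    hit <- grep(paste0("^", key, ": "), lines, value = TRUE)
    if (!length(hit)) return("")
    sub(paste0("^", key, ": "), "", hit[1])
  }
  ov_lines <- grep("^override: ", lines, value = TRUE)
  ov <- list()
  for (l in ov_lines) {
    parts <- strsplit(sub("^override: ", "", l), "\t")[[1]]
    ov[[parts[1]]] <- as.numeric(parts[2])
  }
  make_vp(base, ov,
          phenotypes = trimws(strsplit(get1("phenotypes"), ",")[[1]]),
          id = get1("id"), name = get1("name"), note = get1("note"))
}
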