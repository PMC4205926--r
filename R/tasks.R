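#' Named value set for a parameter group
#'
#' A reusable, labelled assignment for one group of parameters — e.g. the
#' "Drugs" group saved once per dose level — optionally carrying dosing
#' regimens to attach to the protocol.  If the group names a category of
#' the model listing, all parameter names must belong to it.
#'
#' @param group group name.
#' @param label display label, e.g. `"GPR40a 100 mg qd"`.
#' @param values named list of parameter overrides.
#' @param regimens list of [regimen()]s this therapy adds.
#' @param base optional [mdsp_parameters()] used to validate the group.
#' @return object of class `value_set`.
#' @export
value_set <- function(group, label, values = list(), regimens = list(),
                      base = NULL) {
  if (inherits(regimens, "regimen")) regimens <- list(regimens)
  if (!is.null(base) && group %in% base$meta$category && length(values)) {
    cat_of <- base$meta$category[match(names(values), base$meta$name)]
    if (any(is.na(cat_of) | cat_of != group))
      stop("all parameters of a value set must belong to group '", group,
           "'", call. = FALSE)
  }
  structure(list(group = group, label = label, values = values,
                 regimens = regimens), class = "value_set")
}

#' Expand virtual patients and therapy selections into simulation tasks
#'
#' `crossed` mode creates one task per Cartesian combination of patients
#' and per-selection options (`|vps| * prod(|options_i|)` tasks);
#' `combination` mode applies every selected option simultaneously to each
#' patient (`|vps|` tasks).  Ordering is deterministic: patient-major, then
#' option-lexicographic in list order.  In combination mode two options
#' writing the same parameter (or dosing the same drug) is a conflict.
#'
#' @param vps list of virtual patients.
#' @param therapy_options list of selections, each a list of
#'   [value_set()] options.
#' @param mode `"crossed"` or `"combination"`.
#' @param protocol base [protocol()]; option regimens are appended.
#' @param output_spec optional list(outputs=, interval=).
#' @param base [mdsp_parameters()] the patients resolve against.
#' @param model_id plug-in id recorded on each task.
#' @return list of `simulation_task` objects.
#' @export
expand_tasks <- function(vps, therapy_options = list(),
                         mode = c("crossed", "combination"),
                         protocol, output_spec = NULL,
                         base = mdsp_parameters(), model_id = "mdsp") {
  mode <- match.arg(mode)
  if (!length(vps)) return(list())
  for (sel in therapy_options)
    if (!length(sel)) stop("empty therapy selection", call. = FALSE)

  combos <- if (mode == "crossed") {
    if (!length(therapy_options)) list(list())
    else {
      idx <- expand.grid(rev(lapply(therapy_options, seq_along)),
                         KEEP.OUT.ATTRS = FALSE)
      idx <- idx[, rev(seq_len(ncol(idx))), drop = FALSE]
      idx <- idx[do.call(order, as.list(idx)), , drop = FALSE]
      lapply(seq_len(nrow(idx)), function(r)
        lapply(seq_along(therapy_options), function(k)
          therapy_options[[k]][[idx[r, k]]]))
    }
  } else {
    list(unlist(therapy_options, recursive = FALSE))
  }

  tasks <- list()
  for (vp in vps) {
    p_vp <- resolve_vp(vp, base)
    for (opts in combos) {
      p <- p_vp
      proto <- protocol
      seen_par <- character()
      seen_drug <- vapply(proto$regimens, function(r) r$drug, "")
      labels <- character()
      for (o in opts) {
        if (mode == "combination") {
          clash <- intersect(names(o$values), seen_par)
          if (length(clash))
            stop("combination conflict: parameter(s) ",
                 paste(clash, collapse = ", "),
                 " set by more than one therapy", call. = FALSE)
          dclash <- intersect(vapply(o$regimens, function(r) r$drug, ""),
                              seen_drug)
          if (length(dclash))
            stop("combination conflict: drug(s) ",
                 paste(dclash, collapse = ", "),
                 " dosed by more than one therapy", call. = FALSE)
        }
        seen_par <- c(seen_par, names(o$values))
        seen_drug <- c(seen_drug, vapply(o$regimens, function(r) r$drug, ""))
        if (length(o$values)) p <- set_parameters(p, o$values)
        proto$regimens <- c(proto$regimens, o$regimens)
        labels <- c(labels, o$label)
      }
      task <- structure(list(
        task_id = NA_character_, model_id = model_id,
        assignment = p$values, vp_id = vp$id,
        therapy_labels = labels, protocol = proto,
        output_spec = output_spec), class = "simulation_task")
      task$task_id <- .content_hash(serialize_task(task, with_id = FALSE))
      tasks[[length(tasks) + 1]] <- task
    }
  }
  tasks
}

.fmt_num <- function(x) format(x, digits = 17, trim = TRUE, scientific = FALSE)

#' Serialise a simulation task to its input text document
#'
#' Plain text: one `name<TAB>value<TAB>unit` line per model parameter plus
#' protocol and output blocks.  [parse_task()] inverts it bit-exactly, so
#' the document fully defines the simulation.
#'
#' @param task a `simulation_task`.
#' @param with_id include the task id header line (excluded while hashing).
#' @param base [mdsp_parameters()] supplying unit metadata.
#' @return character vector of lines.
#' @export
serialize_task <- function(task, with_id = TRUE, base = mdsp_parameters()) {
  missing <- setdiff(names(base$values), names(task$assignment))
  if (length(missing))
    stop("incomplete parameter assignment; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  units <- base$meta$unit[match(names(task$assignment), base$meta$name)]
  units[is.na(units)] <- "?"
  p <- task$protocol
  lines <- c(
    "# visp-task v1",
    paste0("model: ", task$model_id),
    if (with_id) paste0("task: ", task$task_id),
    paste0("vp: ", task$vp_id),
    paste0("therapies: ", paste(task$therapy_labels, collapse = " + ")),
    "[parameters]",
    sprintf("%s\t%s\t%s", names(task$assignment),
            .fmt_num(task$assignment), units),
    "[protocol]",
    paste0("duration_days\t", .fmt_num(p$duration_days)),
    paste0("run_in_days\t", .fmt_num(p$run_in_days)),
    paste0("output_interval\t", .fmt_num(p$output_interval)),
    paste0("fasting_clock\t", .fmt_num(p$fasting_clock)),
    paste0("auc_window\t", .fmt_num(p$auc_window)),
    paste0("incremental_auc\t", as.integer(p$incremental_auc)),
    paste0("outputs\t", paste(p$outputs, collapse = ",")),
    unlist(lapply(p$meals, function(m)
      sprintf("meal\t%s\t%s\t%s\t%s\t%s", .fmt_num(m$time), .fmt_num(m$kcal),
              .fmt_num(m$carb), .fmt_num(m$fat), .fmt_num(m$prot)))),
    unlist(lapply(p$regimens, function(r) c(
      sprintf("regimen\t%s\t%s", r$drug, .fmt_num(r$morning_time)),
      vapply(r$segments, function(s)
        sprintf("segment\t%s\t%s\t%s", .fmt_num(s$dose_mg), s$schedule,
                .fmt_num(s$n_days)), "")))),
    unlist(lapply(p$ogtt, function(o)
      sprintf("ogtt\t%s\t%s\t%s", .fmt_num(o$glucose_g), .fmt_num(o$day),
              .fmt_num(o$clock_time)))),
    if (!is.null(task$output_spec))
      paste0("output_spec\t",
             paste(task$output_spec$outputs, collapse = ","), "\t",
             .fmt_num(task$output_spec$interval %||% p$output_interval)),
    "[end]")
  lines
}

#' @rdname serialize_task
#' @param lines character vector as produced by [serialize_task()].
#' @export
parse_task <- function(lines, base = mdsp_parameters()) {
  get1 <- function(key) {
    hit <- grep(paste0("^", key, ": "), lines, value = TRUE)
    if (!length(hit)) NA_character_ else sub(paste0("^", key, ": "), "",
                                             hit[1])
  }
  i_par <- which(lines == "[parameters]")
  i_pro <- which(lines == "[protocol]")
  i_end <- which(lines == "[end]")
  if (!length(i_par) || !length(i_pro) || !length(i_end))
    stop("malformed task document", call. = FALSE)

  par_lines <- lines[(i_par + 1):(i_pro - 1)]
  parts <- strsplit(par_lines, "\t")
  assignment <- setNames(vapply(parts, function(x) as.numeric(x[2]), 0),
                         vapply(parts, `[`, "", 1))

  pro_lines <- lines[(i_pro + 1):(i_end - 1)]
  field <- function(key) {
    hit <- grep(paste0("^", key, "\t"), pro_lines, value = TRUE)
    if (!length(hit)) NA_character_ else strsplit(hit[1], "\t")[[1]][2]
  }
  meals <- lapply(grep("^meal\t", pro_lines, value = TRUE), function(l) {
    x <- as.numeric(strsplit(l, "\t")[[1]][-1])
    meal(x[1], x[2], x[3], x[4], x[5])
  })
  regimens <- list()
  cur <- NULL
  for (l in pro_lines) {
    x <- strsplit(l, "\t")[[1]]
    if (x[1] == "regimen") {
      if (!is.null(cur)) regimens[[length(regimens) + 1]] <-
          regimen(cur$drug, cur$segments, cur$morning)
      cur <- list(drug = x[2], morning = as.numeric(x[3]), segments = list())
    } else if (x[1] == "segment") {
      cur$segments[[length(cur$segments) + 1]] <-
        list(dose_mg = as.numeric(x[2]), schedule = x[3],
             n_days = as.numeric(x[4]))
    }
  }
  if (!is.null(cur)) regimens[[length(regimens) + 1]] <-
      regimen(cur$drug, cur$segments, cur$morning)
  ogtt <- lapply(grep("^ogtt\t", pro_lines, value = TRUE), function(l) {
    x <- as.numeric(strsplit(l, "\t")[[1]][-1])
    build_ogtt(x[1], x[2], x[3])
  })
  proto <- protocol(
    duration_days = as.numeric(field("duration_days")),
    meals = meals, regimens = regimens, ogtt = ogtt,
    outputs = strsplit(field("outputs"), ",")[[1]],
    output_interval = as.numeric(field("output_interval")),
    run_in_days = as.numeric(field("run_in_days")),
    fasting_clock = as.numeric(field("fasting_clock")),
    auc_window = as.numeric(field("auc_window")),
    incremental_auc = field("incremental_auc") == "1")
  os_line <- grep("^output_spec\t", pro_lines, value = TRUE)
  output_spec <- if (length(os_line)) {
    x <- strsplit(os_line[1], "\t")[[1]]
    list(outputs = strsplit(x[2], ",")[[1]], interval = as.numeric(x[3]))
  }
  therapies <- get1("therapies")
  structure(list(
    task_id = get1("task"), model_id = get1("model"),
    assignment = assignment, vp_id = get1("vp"),
    therapy_labels = if (is.na(therapies) || !nzchar(therapies)) character()
                     else strsplit(therapies, " + ", fixed = TRUE)[[1]],
    protocol = proto, output_spec = output_spec),
    class = "simulation_task")
}
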