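# Shared fixtures.  Heavier objects (steady states) are computed once per
# test run and reused.

healthy_params <- mdsp_parameters()
t2dm_params <- resolve_vp(t2dm_representative_vp())

.ss_cache <- new.env(parent = emptyenv())
cached_ss <- function(params, key) {
  if (is.null(.ss_cache[[key]]))
    .ss_cache[[key]] <- steady_state(params)
  .ss_cache[[key]]
}
healthy_ss <- function() cached_ss(healthy_params, "healthy")
t2dm_ss <- function() cached_ss(t2dm_params, "t2dm")

# a state whose insulin-action compartments are equilibrated to a given
# insulin level (quasi-static insulin scan)
state_at_insulin <- function(params, I, ...) {
  v <- params$values
  metabolic_state(params, I_plasma = I,
                  I_portal = I * v[["I_portal_ref"]] / v[["I_ref"]],
                  E_liver = I / v[["I_ref"]], E_muscle = I / v[["I_ref"]],
                  ...)
}

# minimal protocol used by manager-level tests: cheap to simulate
tiny_protocol <- function(...) {
  protocol(duration_days = 1, meals = list(meal(8, 300)),
           outputs = c("G_plasma", "I_plasma"), output_interval = 1,
           run_in_days = 0, ...)
}

# toy one-compartment decay model plug-in: exercises the manager's
# model-agnostic code path without the metabolic model
toy_plugin <- function(fail_when = function(assignment) FALSE) {
  template <- list(
    values = c(y0 = 10, k = 0.5),
    meta = data.frame(name = c("y0", "k"), unit = c("au", "1/h"),
                      category = c("DOSE", "RATE"),
                      description = c("initial amount", "decay rate")))
  entry <- function(assignment, protocol, output_spec = NULL) {
    if (fail_when(assignment)) stop("toy model failure")
    tt <- seq(0, protocol$duration_days * 24, by = protocol$output_interval)
    data.frame(time = tt, y = assignment[["y0"]] * exp(-assignment[["k"]] * tt))
  }
  model_plugin("toy", template, entry)
}

toy_task <- function(k = 0.5, y0 = 10, id = "toy") {
  task <- structure(list(
    task_id = NA_character_, model_id = "toy",
    assignment = c(y0 = y0, k = k), vp_id = id,
    therapy_labels = character(), protocol = tiny_protocol(),
    output_spec = NULL), class = "simulation_task")
  task
}
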