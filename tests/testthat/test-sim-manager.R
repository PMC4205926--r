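mk_store <- function(n = 3, tag = "t2dm") {
  base <- mdsp_parameters()
  lapply(seq_len(n), function(i)
    make_vp(base, list(), tag, id = paste0(tag, i)))
}

therapy <- function(label, dose) {
  value_set("Drugs", label,
            regimens = regimen("metformin",
                               list(list(dose_mg = dose, schedule = "qd",
                                         n_days = 1))))
}

test_that("task expansion reproduces the crossed and combination counts", {
  vps <- mk_store(3)
  proto <- tiny_protocol()
  # 3 patients, one therapy -> 3 tasks
  t1 <- expand_tasks(vps, list(list(therapy("A", 500))), "crossed", proto)
  expect_length(t1, 3)
  # two therapy options crossed -> 6 tasks
  t2 <- expand_tasks(vps, list(list(therapy("A", 500), therapy("B", 1000))),
                     "crossed", proto)
  expect_length(t2, 6)
  # combination: both applied to each patient -> 3 tasks
  t3 <- expand_tasks(vps, list(list(
    therapy("A", 500),
    value_set("Drugs2", "B", regimens = regimen(
      "tak875", list(list(dose_mg = 50, schedule = "qd", n_days = 1)))))),
    "combination", proto)
  expect_length(t3, 3)
  expect_length(t3[[1]]$protocol$regimens, 2)
  expect_identical(t3[[1]]$therapy_labels, c("A", "B"))
})

test_that("crossed expansion matches the Cartesian oracle and ordering", {
  set.seed(5)
  proto <- tiny_protocol()
  for (rep in 1:5) {
    n_vp <- sample(1:3, 1)
    sizes <- sample(1:3, sample(1:3, 1), replace = TRUE)
    vps <- mk_store(n_vp)
    options <- lapply(seq_along(sizes), function(k)
      lapply(seq_len(sizes[k]), function(j)
        value_set("G", sprintf("s%d_o%d", k, j),
                  values = list())))
    tasks <- expand_tasks(vps, options, "crossed", proto)
    expect_length(tasks, n_vp * prod(sizes))
    # patient-major deterministic ordering
    expect_identical(vapply(tasks, `[[`, "", "vp_id"),
                     rep(vapply(vps, `[[`, "", "id"), each = prod(sizes)))
    labels <- vapply(tasks, function(t)
      paste(t$therapy_labels, collapse = "+"), "")
    oracle <- apply(expand.grid(rev(lapply(sizes, seq_len)))[,
                      rev(seq_along(sizes)), drop = FALSE], 1, function(ix)
      paste(sprintf("s%d_o%d", seq_along(sizes), ix), collapse = "+"))
    expect_identical(labels[seq_len(prod(sizes))], unname(oracle))
  }
  expect_identical(expand_tasks(list(), list(), "crossed", tiny_protocol()),
                   list())
})

test_that("combination conflicts on a shared parameter are rejected", {
  vps <- mk_store(1)
  proto <- tiny_protocol()
  o1 <- value_set("G", "low", values = list(renal_threshold = 9))
  o2 <- value_set("G", "high", values = list(renal_threshold = 12))
  expect_error(expand_tasks(vps, list(list(o1), list(o2)), "combination",
                            proto), "renal_threshold")
  expect_error(expand_tasks(vps, list(list(therapy("A", 250)),
                                      list(therapy("B", 500))),
                            "combination", proto), "metformin")
  # the same two options crossed are fine
  expect_length(expand_tasks(vps, list(list(o1), list(o2)), "crossed", proto),
                1)
})

test_that("task documents round-trip bit-exactly", {
  vps <- mk_store(1)
  proto <- protocol(duration_days = 3,
                    regimens = list(regimen("metformin", list(
                      list(dose_mg = 500, schedule = "bid", n_days = 3)))),
                    ogtt = build_ogtt(75, 1, 8),
                    outputs = c("G_plasma", "I_plasma"),
                    run_in_days = 1)
  task <- expand_tasks(vps, list(), "crossed", proto)[[1]]
  doc <- serialize_task(task)
  task2 <- parse_task(doc)
  expect_identical(task2$task_id, task$task_id)
  expect_identical(task2$assignment, task$assignment)
  expect_identical(task2$vp_id, task$vp_id)
  expect_identical(serialize_task(task2), doc)
  # identical content hashes to the identical id
  expect_identical(
    visp:::.content_hash(serialize_task(task2, with_id = FALSE)),
    task$task_id)

  # tasks differing in one parameter differ in exactly one document line
  vpB <- make_vp(mdsp_parameters(), list(renal_threshold = 11), "t2dm",
                 id = vps[[1]]$id)
  taskB <- expand_tasks(list(vpB), list(), "crossed", proto)[[1]]
  docB <- serialize_task(taskB, with_id = FALSE)
  docA <- serialize_task(task, with_id = FALSE)
  expect_identical(sum(docA != docB), 1L)

  bad <- task
  bad$assignment <- bad$assignment[-1]
  expect_error(serialize_task(bad), names(task$assignment)[1])
})

test_that("batches run isolated tasks and are worker-count invariant", {
  plugin <- toy_plugin()
  tasks <- lapply(c(0.2, 0.5, 1, 2, 3, 5), function(k) toy_task(k = k))
  r1 <- run_batch(tasks, plugin, workers = 1)
  r4 <- run_batch(tasks, plugin, workers = 4)
  expect_length(r1, 6)
  for (i in seq_along(r1)) expect_equal(r1[[i]]$y, r4[[i]]$y)

  expect_identical(run_batch(list(), plugin), list())

  failing <- toy_plugin(fail_when = function(a) a[["k"]] > 4)
  rf <- run_batch(tasks, failing, workers = 2)
  fails <- vapply(rf, inherits, TRUE, "task_failure")
  expect_identical(sum(fails), 1L)
  expect_match(rf[[which(fails)]]$error, "toy model failure")
  expect_s3_class(rf[[1]], "data.frame")
})

test_that("the metabolic plug-in honours the task contract", {
  plugin <- mdsp_plugin()
  expect_error(plugin$entry(c(G_ref = 5), tiny_protocol()), "incomplete")
  vps <- list(t2dm_representative_vp())
  tasks <- expand_tasks(vps, list(), "crossed", tiny_protocol())
  res <- run_batch(tasks, plugin)
  expect_s3_class(res[[1]], "data.frame")
  expect_true(all(c("time", "G_plasma", "I_plasma") %in% names(res[[1]])))
  expect_true(all(diff(res[[1]]$time) > 0))
})

test_that("schema validation flags unknown names, duplicates, categories", {
  plugin <- mdsp_plugin()
  ctl <- data.frame(
    section = "Meals",
    parameter = c("meal_kcal", "meal_time_1", "nonexistent_par"),
    label = c("Calories", "Breakfast time", "Ghost"),
    control = "text",
    category = c("DOSE", "TIME", "DOSE"),
    row = c(1, 1, 2), column = c(1, 2, 1))
  rep <- validate_schema(exposed_schema(ctl), plugin)
  expect_identical(rep$unknown_parameters, "nonexistent_par")
  expect_false(rep$valid)

  dup <- ctl[c(1, 1), ]
  rep2 <- validate_schema(exposed_schema(dup), plugin)
  expect_length(rep2$duplicate_cells, 1)

  mism <- ctl[1, ]
  mism$category <- "TIME"
  expect_identical(validate_schema(exposed_schema(mism), plugin)
                   $category_mismatches, "meal_kcal")

  good <- ctl[1:2, ]
  repg <- validate_schema(exposed_schema(good), plugin)
  expect_true(repg$valid)

  expect_error(exposed_schema(ctl[, -1]), "section")
  expect_error(exposed_schema(transform(ctl, control = "slider")), "control")

  # keyword filter oracle: plain substring match over the listing
  hits <- filter_parameters(plugin, "meal")
  oracle <- grep("meal", names(mdsp_parameters()$values), value = TRUE,
                 fixed = TRUE)
  expect_identical(hits, oracle)
  expect_true(all(c("meal_kcal", "meal_time_1") %in% hits))
})

test_that("unit conversion is exact and invertible", {
  expect_identical(convert_units(500, "DOSE", "mg", "g"), 0.5)
  expect_identical(convert_units(24, "TIME", "h", "day"), 1)
  x <- c(0.3, 1, 250)
  expect_identical(convert_units(convert_units(x, "TIME", "h", "min"),
                                 "TIME", "min", "h"), x)
  expect_error(convert_units(1, "DOSE", "mg", "stone"), "unknown unit")
  expect_error(convert_units(1, "MASS", "mg", "g"), "category")
})

test_that("stored results reload losslessly and detect corruption", {
  plugin <- toy_plugin()
  tasks <- lapply(c(0.3, 0.7, 1.5), function(k) toy_task(k = k))
  for (i in seq_along(tasks)) tasks[[i]]$task_id <- sprintf("id%02d", i)
  results <- run_batch(tasks, plugin)
  dir <- tempfile("batch")
  manifest <- store_results(results, dir)
  entries <- jsonlite::read_json(manifest)
  expect_length(entries, 3)

  back <- load_results(manifest)
  for (i in 1:3)
    expect_equal(back[[i]]$y, results[[i]]$y, tolerance = 1e-12)

  # corrupt one file: the integrity check names the task
  f <- file.path(dir, entries[[2]]$file)
  writeLines(sub("0", "9", readLines(f)), f)
  expect_error(load_results(manifest), "id02")
})
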