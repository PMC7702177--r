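test_that("text composer mirrors author metadata and validates cleanly", {
  bco <- with_frozen_clock(compose_from_text(demo_meta()))
  expect_identical(bco$provenance_domain$name, "demo object")
  expect_length(bco$provenance_domain$contributors, 2)
  expect_length(bco$usability_domain, 2)
  report <- validate(bco)
  expect_true(report$passed)
  expect_identical(nrow(report$issues), 0L)
  # determinism under frozen clock
  expect_identical(bco$etag,
                   with_frozen_clock(compose_from_text(demo_meta()))$etag)
})

test_that("author metadata requires a provenance name; YAML config round trip", {
  expect_error(author_metadata(provenance = list()), "provenance name")
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("provenance:",
               "  name: from yaml",
               "  version: '3.0'",
               "usability:",
               "  - first statement",
               "extension:",
               "  - extension_schema: https://example.org/ext.json",
               "    payload: {k: v}"), f)
  meta <- read_author_metadata(f)
  expect_identical(meta$provenance$name, "from yaml")
  bco <- with_frozen_clock(compose_from_text(meta))
  expect_length(bco$extension_domain, 1)
  expect_true(validate(bco)$passed)
})

test_that("CWL composer populates description/parametric/execution/io domains", {
  wf <- demo_workflow(n_steps = 4L, seed = 2L)
  bco <- with_frozen_clock(compose_from_cwl(wf, demo_meta(),
                                            workflow_path = "wf.cwl.json"))
  steps <- bco$description_domain$pipeline_steps
  expect_length(steps, 4)
  expect_identical(vapply(steps, `[[`, integer(1), "step_number"), 1:4)
  expect_identical(unlist(bco$execution_domain$script), "wf.cwl.json")
  # every generated step has a scalar `threads` default -> parametric entries
  expect_length(bco$parametric_domain, 4)
  expect_setequal(vapply(bco$parametric_domain, `[[`, integer(1),
                         "step_number"), 1:4)
  # io domain lists File-typed workflow ports prospectively
  n_file_in <- sum(vapply(wf$inputs, `[[`, logical(1), "is_file"))
  expect_length(bco$io_domain$input_subdomain, n_file_in)
  expect_true(validate(bco)$passed)
})

test_that("0-step workflow composes to a schema-valid BCO", {
  wf <- demo_workflow(n_steps = 0L, n_inputs = 1L, n_outputs = 1L)
  bco <- with_frozen_clock(compose_from_cwl(wf, demo_meta()))
  expect_length(bco$description_domain$pipeline_steps, 0)
  expect_true(validate(bco)$passed)
})

test_that("description step count equals workflow step count over fixtures", {
  for (n in c(0L, 1L, 4L, 10L)) {
    wf <- demo_workflow(n_steps = n, seed = n + 1L)
    bco <- with_frozen_clock(compose_from_cwl(wf, demo_meta()))
    expect_length(bco$description_domain$pipeline_steps, n)
  }
})

test_that("task composer captures io counts, parameters, and platform", {
  wf <- demo_workflow(n_steps = 3L, seed = 4L)
  task <- generate_task(wf, 3L, 2L, seed = 4L)
  bco <- with_frozen_clock(compose_from_task(task, wf, demo_meta()))
  expect_length(bco$io_domain$input_subdomain, 3)
  expect_length(bco$io_domain$output_subdomain, 2)
  expect_true("mock-platform" %in% unlist(bco$description_domain$platform))
  expect_identical(bco$execution_domain$software_prerequisites[[1]]$name,
                   wf$id)
  # actual task parameters (one `threads` per step) land in parametric
  expect_length(bco$parametric_domain, 3)
  expect_true(validate(bco)$passed)
})

test_that("array-valued file inputs expand one entry per file", {
  wf <- demo_workflow(n_steps = 1L, n_inputs = 1L, seed = 9L)
  task <- generate_task(wf, 10L, 0L, seed = 9L)
  bco <- with_frozen_clock(compose_from_task(task, wf, demo_meta()))
  expect_length(bco$io_domain$input_subdomain, 10)
  expect_length(bco$io_domain$output_subdomain, 0)
  expect_true(validate(bco)$passed)
})

test_that("io entry counts equal expanded task file counts (property)", {
  set.seed(31)
  for (i in 1:8) {
    n_in <- sample(0:30, 1); n_out <- sample(0:30, 1)
    wf <- demo_workflow(n_steps = sample(1:4, 1), seed = i)
    task <- generate_task(wf, n_in, n_out, seed = i + 100L)
    bco <- with_frozen_clock(compose_from_task(task, wf, demo_meta()))
    expect_length(bco$io_domain$input_subdomain, n_in)
    expect_length(bco$io_domain$output_subdomain, n_out)
  }
})

test_that("non-completed tasks are rejected; step mismatches warn but proceed", {
  wf <- demo_workflow(n_steps = 2L, seed = 6L)
  task <- generate_task(wf, 2L, 1L, seed = 6L)
  bad <- task; bad$status <- "failed"
  expect_error(with_frozen_clock(compose_from_task(bad, wf, demo_meta())),
               "completed")
  mism <- task
  mism$inputs[[length(mism$inputs) + 1L]] <-
    list(name = "ghost_step/param", value = 1L)
  expect_warning(
    bco <- with_frozen_clock(compose_from_task(mism, wf, demo_meta())),
    "does not match")
  expect_true(validate(bco)$passed)
})

test_that("mock adapter serves fixtures and distinguishes error kinds", {
  task <- fetch_task(mock_adapter(), "task-1")
  expect_s3_class(task, "task_record")
  expect_identical(task$status, "completed")
  expect_identical(task$platform_name, "mock-platform")
  expect_identical(task$app_revision, "3")
  expect_length(task$inputs, 5)
  expect_length(task$outputs, 2)
  expect_error(fetch_task(mock_adapter(), "nope"),
               class = "bcokit_not_found_error")
  expect_error(fetch_task(mock_adapter(dir = "/no/such/dir"), "task-1"),
               class = "bcokit_transport_error")
})

test_that("bundled CGC-shaped fixture composes end to end", {
  wf <- parse_cwl(paste(readLines(rnaseq_fixture_path(), warn = FALSE),
                        collapse = "\n"))
  task <- fetch_task(mock_adapter(), "task-1")
  bco <- with_frozen_clock(compose_from_task(task, wf, demo_meta(),
                                             workflow_path = "rnaseq.cwl.json"))
  expect_length(bco$io_domain$input_subdomain, 3)  # 2 array files + 1 scalar file
  expect_length(bco$io_domain$output_subdomain, 2)
  expect_length(bco$parametric_domain, 3)
  expect_true(validate(bco)$passed)
})
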