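test_that("events validate their class, targets and move properties", {
  st <- pheno_store()
  assert_class(st, c("plot1", "plot2"), "Plot")
  ev <- record_event(st, "Incident", "2017-05-20", c("plot1", "plot2"),
    description = "Plots lodged after the storm"
  )
  expect_equal(sort(ev$concerns[[1]]), c("plot1", "plot2"))
  # linked into the graph
  expect_true(all(c("plot1", "plot2") %in%
    st$triples$object[st$triples$subject == ev$uri]))
  expect_error(
    record_event(st, "Incident", "2017-05-20", "ghost"),
    "unknown object"
  )
  expect_error(
    record_event(st, "Incident", "2017-05-20", character()),
    "non-empty"
  )
  expect_error(record_event(st, "Plant", "2017-05-20", "plot1"), "Event subtree")
  expect_error(
    record_event(st, "MoveTo", "2017-05-20", "plot1"),
    "from_location"
  )
  expect_error(
    record_event(st, "MoveTo", "2017-05-20", "plot1",
      properties = list(from_location = "a", to_location = "a")
    ),
    "change location or position"
  )
  # same location but different position is a legal move
  expect_silent(record_event(st, "MoveTo", "2017-05-20", "plot1",
    properties = list(
      from_location = "a", to_location = "a",
      from_position = "x1 y1", to_position = "x2 y2"
    )
  ))
})

test_that("re-recording an event under the same URI does not duplicate it", {
  st <- pheno_store()
  assert_class(st, "plot1", "Plot")
  for (i in 1:3) {
    record_event(st, "Incident", "2017-05-20", "plot1", uri = "event:e1")
  }
  expect_equal(nrow(events_for(st, "plot1")), 1L)
})

test_that("annotations validate motivation, body and targets", {
  st <- pheno_store()
  assert_class(st, "plant816", "Plant")
  a <- annotate(st, "agent:lcabrera", "suspicious replicate", "plant816",
    motivation = "flagging", created = "2017-06-01"
  )
  expect_equal(a$motivation, "flagging")
  expect_error(annotate(st, "agent:x", "", "plant816"), "non-empty")
  expect_error(annotate(st, "agent:x", "note", character()), "non-empty")
  expect_error(annotate(st, "agent:x", "note", "ghost"), "unknown object")
  expect_error(
    annotate(st, "agent:x", "note", "plant816", motivation = "liking"),
    "should be one of"
  )
  # data-point targets carry object, variable and timestamp
  dp <- list(list(
    object = "plant816", variable = "var:leaf_area",
    timestamp = "2017-05-30T12:00:00Z"
  ))
  b <- annotate(st, "agent:x", "odd point", dp, motivation = "commenting")
  expect_equal(b$targets[[1]][[1]]$variable, "var:leaf_area")
})

test_that("events inherit down part-of chains, not up", {
  st <- lodging_store()
  # leaves of the lodged plot see the incident through inheritance only
  got <- events_for(st, "plot1_leaf1", class_filter = "Incident", inherit = TRUE)
  expect_equal(got$uri, "event:lodging")
  expect_equal(nrow(events_for(st, "plot1_leaf1", inherit = FALSE)), 0L)
  # leaves of the other plot never see it
  expect_equal(
    nrow(events_for(st, "plot2_leaf1", class_filter = "Incident", inherit = TRUE)),
    0L
  )
  # subsumption-aware filter: Trouble matches the Incident
  expect_equal(
    events_for(st, "plot1", class_filter = "Trouble")$uri,
    "event:lodging"
  )
  expect_error(events_for(st, "plot1", class_filter = "Storm"), "unknown class")
  # inherited queries are a superset of direct ones
  direct <- events_for(st, "plot1", inherit = FALSE)$uri
  inherited <- events_for(st, "plot1", inherit = TRUE)$uri
  expect_true(all(direct %in% inherited))
})

test_that("the two-installation worked example yields a 10-day middle interval", {
  st <- tracking_example_store()
  iv <- residence_intervals(st, "plant262", "2017-04-13", "2017-06-02")
  expect_equal(nrow(iv), 3L)
  expect_equal(iv$location, c("inst1", "inst2", "inst1"))
  expect_equal(interval_days(iv)[2], 10)
  # half-open and contiguous
  expect_equal(iv$end[-3], iv$start[-1])
})

test_that("an object that never moves occupies a single interval", {
  st <- pheno_store()
  assert_class(st, c("inst1", "p1"), c("Installation", "Plant"))
  add_triple(st, "p1", "locatedIn", "inst1")
  iv <- residence_intervals(st, "p1", "2017-04-13", "2017-06-02")
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$location, "inst1")
  expect_equal(sum(interval_days(iv)), 50)
})

test_that("contradictory or ambiguous schedules raise errors", {
  st <- pheno_store()
  assert_class(st, c("inst1", "inst2", "p1"), c("Installation", "Installation", "Plant"))
  add_triple(st, "p1", "locatedIn", "inst1")
  record_event(st, "MoveTo", "2017-05-01", "p1",
    properties = list(from_location = "inst2", to_location = "inst1")
  )
  expect_error(
    residence_intervals(st, "p1", "2017-04-13", "2017-06-02"),
    "inconsistent move.*inst2.*inst1"
  )

  st2 <- pheno_store()
  assert_class(st2, c("inst1", "inst2", "inst3", "p1"),
    c(rep("Installation", 3), "Plant"))
  add_triple(st2, "p1", "locatedIn", "inst1")
  record_event(st2, "MoveTo", "2017-05-01", "p1",
    properties = list(from_location = "inst1", to_location = "inst2")
  )
  record_event(st2, "MoveTo", "2017-05-01", "p1",
    properties = list(from_location = "inst2", to_location = "inst3")
  )
  expect_error(
    residence_intervals(st2, "p1", "2017-04-13", "2017-06-02"),
    "ambiguous"
  )

  st3 <- pheno_store()
  assert_class(st3, "p1", "Plant")
  expect_error(
    residence_intervals(st3, "p1", "2017-04-13", "2017-06-02"),
    "no placement"
  )
})

test_that("random schedules partition the window exactly", {
  for (seed in 1:30) {
    sc <- random_schedule_store(seed)
    iv <- residence_intervals(sc$store, "obj", UTC("2020-01-01"), UTC("2020-03-01"))
    expect_equal(nrow(iv), sc$n_moves + 1L, label = paste("seed", seed))
    expect_true(all(iv$start < iv$end))
    if (nrow(iv) > 1) {
      expect_equal(iv$end[-nrow(iv)], iv$start[-1], label = paste("seed", seed))
      expect_true(all(iv$location[-1] != iv$location[-nrow(iv)]))
    }
    expect_equal(iv$start[1], UTC("2020-01-01"))
    expect_equal(iv$end[nrow(iv)], sc$end)
    expect_equal(
      sum(interval_days(iv)),
      as.numeric(difftime(sc$end, UTC("2020-01-01"), units = "days")),
      label = paste("seed", seed)
    )
  }
})
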