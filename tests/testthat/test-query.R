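# A ten-plant fixture with hand-set leaf area and height maxima.
ten_plant_store <- function() {
  st <- pheno_store()
  plants <- sprintf("plant%02d", 1:10)
  assert_class(st, plants, "Plant")
  la_max <- c(0.45, 0.62, 0.58, 0.71, 0.30, 0.66, 0.59, 0.80, 0.55, 0.61)
  h_max <- c(1400, 1450, 1600, 1300, 1200, 1520, 1480, 1700, 1490, 1350)
  obs <- do.call(rbind, lapply(1:10, function(i) {
    data.frame(
      object = plants[i],
      variable = rep(c("var:leaf_area", "var:plant_height"), each = 3),
      timestamp = rep(UTC("2017-05-01") + (0:2) * 86400, 2),
      value = c(la_max[i] * c(0.5, 0.8, 1), h_max[i] * c(0.5, 0.8, 1))
    )
  }))
  add_observations(st, obs)
  list(store = st, plants = plants, la_max = la_max, h_max = h_max)
}

test_that("value constraints reproduce a direct-scan oracle", {
  fx <- ten_plant_store()
  got <- select_objects(fx$store, query_spec(
    "Plant",
    data = list(where_value("var:leaf_area", ">", 0.6, aggregator = "max"))
  ))
  expect_equal(got, sort(fx$plants[fx$la_max > 0.6]))
  # and/or: union of leaf area > 0.6 and height > 1500
  got_or <- select_objects(fx$store, query_spec(
    "Plant",
    data = list(
      where_value("var:leaf_area", ">", 0.6, aggregator = "max"),
      where_value("var:plant_height", ">", 1500, aggregator = "max")
    ),
    data_combinator = "OR"
  ))
  expect_equal(got_or, sort(fx$plants[fx$la_max > 0.6 | fx$h_max > 1500]))
  got_and <- select_objects(fx$store, query_spec(
    "Plant",
    data = list(
      where_value("var:leaf_area", ">", 0.6, aggregator = "max"),
      where_value("var:plant_height", ">", 1500, aggregator = "max")
    ),
    data_combinator = "AND"
  ))
  expect_equal(got_and, sort(fx$plants[fx$la_max > 0.6 & fx$h_max > 1500]))
  expect_error(
    select_objects(fx$store, query_spec(
      "Plant",
      data = list(where_value("var:biomass", ">", 1))
    )),
    "unknown variable"
  )
})

test_that("aggregators differ: any vs latest vs mean", {
  st <- pheno_store()
  assert_class(st, "p1", "Plant")
  add_observations(st, data.frame(
    object = "p1", variable = "var:x",
    timestamp = UTC("2017-05-01") + (0:2) * 86400,
    value = c(10, 1, 2)
  ))
  q <- function(agg) {
    select_objects(st, query_spec(
      "Plant",
      data = list(where_value("var:x", ">", 5, aggregator = agg))
    ))
  }
  expect_equal(q("any"), "p1") # the first point passes
  expect_equal(q("latest"), character()) # last value is 2
  expect_equal(q("max"), "p1")
  expect_equal(q("mean"), character()) # mean 4.33
})

test_that("semantic constraints select images of lodged plots", {
  st <- lodging_store()
  got <- select_objects(st, query_spec(
    "Image",
    semantic = list(has_relation(c("concerns", "^concerns"), "event:lodging"))
  ))
  # image -> plot (concerns) -> lodging event (inverse concerns)
  expect_equal(got, "img_plot1")
  # equivalent: images whose plot has an Incident, via two single constraints
  lodged_plots <- select_objects(st, query_spec(
    "Plot",
    semantic = list(has_event("Incident"))
  ))
  expect_equal(lodged_plots, "plot1")
  imgs <- select_objects(st, query_spec(
    "Image",
    semantic = list(has_relation("concerns", "plot1"))
  ))
  expect_equal(imgs, "img_plot1")
})

test_that("numeric comparators on text variables raise a type error", {
  st <- pheno_store()
  assert_class(st, "p1", "Plant")
  add_observations(st, data.frame(
    object = "p1", variable = "var:colour",
    timestamp = UTC("2017-05-01"), value_text = "green"
  ))
  expect_error(
    select_objects(st, query_spec(
      "Plant",
      data = list(where_value("var:colour", ">", 3))
    )),
    "text-valued"
  )
  got <- select_objects(st, query_spec(
    "Plant",
    data = list(where_value("var:colour", "=", "green"))
  ))
  expect_equal(got, "p1")
})

test_that("empty stores and unknown classes behave predictably", {
  st <- pheno_store()
  expect_equal(select_objects(st, query_spec("Plant")), character())
  expect_error(select_objects(st, query_spec("Gizmo")), "unknown class")
})

test_that("AND is intersection, OR is union, > is monotone (property)", {
  withr::with_seed(31, {
    for (rep in 1:15) {
      st <- pheno_store()
      n <- sample(5:12, 1)
      plants <- paste0("p", seq_len(n))
      assert_class(st, plants, "Plant")
      add_observations(st, data.frame(
        object = rep(plants, each = 4),
        variable = rep(c("var:a", "var:a", "var:b", "var:b"), n),
        timestamp = rep(UTC("2017-05-01") + (0:3) * 86400, n),
        value = round(stats::runif(4 * n, 0, 10), 2)
      ))
      c1 <- where_value("var:a", ">", stats::runif(1, 2, 8), aggregator = "max")
      c2 <- where_value("var:b", "<", stats::runif(1, 2, 8), aggregator = "mean")
      single <- function(cc) select_objects(st, query_spec("Plant", data = list(cc)))
      both_and <- select_objects(st, query_spec("Plant", data = list(c1, c2)))
      both_or <- select_objects(st, query_spec("Plant",
        data = list(c1, c2),
        data_combinator = "OR"
      ))
      expect_equal(both_and, sort(intersect(single(c1), single(c2))))
      expect_equal(both_or, sort(union(single(c1), single(c2))))
      # raising a strict threshold never adds objects
      lo <- single(where_value("var:a", ">", 3, aggregator = "max"))
      hi <- single(where_value("var:a", ">", 5, aggregator = "max"))
      expect_true(all(hi %in% lo))
    }
  })
})

test_that("inherited-event results connect to an event-bearing ancestor", {
  st <- lodging_store()
  got <- select_objects(st, query_spec(
    "Leaf",
    semantic = list(has_event("Incident", inherit = TRUE))
  ))
  expect_equal(got, sort(paste0("plot1_leaf", 1:3)))
  for (leaf in got) {
    ancestors <- kg_related(st, leaf, "isPartOf")
    has_ev <- any(vapply(ancestors, function(a) {
      nrow(events_for(st, a, class_filter = "Incident")) > 0
    }, logical(1)))
    expect_true(has_ev, label = leaf)
  }
})

test_that("sensors exceeding a threshold are found, windows respected", {
  st <- pheno_store()
  v <- "var:temp"
  withr::with_seed(5, {
    for (i in 1:10) {
      ts <- seq(UTC("2017-06-01"), by = 3600, length.out = 48)
      peak <- if (i == 7) 41 else stats::runif(1, 30, 39)
      vals <- stats::runif(48, 15, 25)
      vals[25] <- peak
      add_sensor_series(st, paste0("s", i), v, data.frame(timestamp = ts, value = vals))
    }
  })
  expect_equal(sensors_exceeding(st, v, 40), "s7")
  expect_equal(sensors_exceeding(st, v, 50), character())
  # a window that excludes the exceedance hour
  expect_equal(
    sensors_exceeding(st, v, 40, window = c("2017-06-01", "2017-06-02")),
    character()
  )
})

test_that("query specifications parse from JSON", {
  fx <- ten_plant_store()
  json <- '{
    "target_class": "Plant",
    "data_combinator": "OR",
    "data": [
      {"variable": "var:leaf_area", "comparator": ">", "threshold": 0.6,
       "aggregator": "max"},
      {"variable": "var:plant_height", "comparator": ">", "threshold": 1500,
       "aggregator": "max"}
    ]
  }'
  spec <- query_from_json(json)
  expect_equal(
    select_objects(fx$store, spec),
    sort(fx$plants[fx$la_max > 0.6 | fx$h_max > 1500])
  )
})
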