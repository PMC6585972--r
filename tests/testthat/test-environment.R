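test_that("sensor assignments reject overlaps and honour half-open spans", {
  st <- pheno_store()
  v <- "var:temp"
  assign_sensor(st, "station1", v, "sA", "2017-04-01", "2017-05-01")
  assign_sensor(st, "station1", v, "sB", "2017-05-01", NA) # replacement, abutting
  expect_error(
    assign_sensor(st, "station1", v, "sC", "2017-04-20", "2017-05-10"),
    "overlaps.*sA|overlaps.*sB"
  )
  # a replacement day: the point at the boundary instant belongs to B
  assert_class(st, c("inst1", "p"), c("Installation", "Plant"))
  add_triple(st, "p", "locatedIn", "station1")
  add_sensor_series(st, "sA", v, data.frame(
    timestamp = UTC(c("2017-04-30 23:00:00", "2017-05-01 00:00:00")),
    value = c(1, 999)
  ))
  add_sensor_series(st, "sB", v, data.frame(
    timestamp = UTC("2017-05-01 00:00:00"), value = c(2)
  ))
  ss <- stitch(st, "p", v, c("2017-04-30", "2017-05-02"))
  expect_equal(ss$value, c(1, 2))
  expect_equal(ss$sensor, c("sA", "sB"))
  # sA's point at the boundary instant is outside its span: lost, not served
  expect_equal(attr(ss, "lost_points"), 1L)
})

test_that("series timestamps must be strictly increasing and finite", {
  st <- pheno_store()
  expect_error(
    add_sensor_series(st, "s", "v", data.frame(
      timestamp = UTC(c("2017-01-02", "2017-01-01")), value = c(1, 2)
    )),
    "strictly increasing"
  )
  expect_error(
    add_sensor_series(st, "s", "v", data.frame(
      timestamp = UTC("2017-01-01"), value = NaN
    )),
    "finite"
  )
})

test_that("stitching switches source at the move instants", {
  st <- tracking_example_store(temp1 = 20, temp2 = 30)
  ss <- stitch(st, "plant262", "var:air_temperature", c("2017-04-13", "2017-06-02"))
  move_out <- UTC("2017-05-19")
  move_back <- UTC("2017-05-29")
  expect_true(all(ss$value[ss$timestamp < move_out] == 20))
  expect_true(all(ss$value[ss$timestamp >= move_out & ss$timestamp < move_back] == 30))
  expect_true(all(ss$value[ss$timestamp >= move_back] == 20))
  # point count equals the sum of in-interval source points; nothing lost
  expect_equal(nrow(ss), 50 * 24)
  expect_equal(attr(ss, "lost_points"), 0L)
  expect_equal(nrow(attr(ss, "gaps")), 0L)
  expect_true(!is.unsorted(ss$timestamp, strictly = TRUE))
})

test_that("an unmoved object's stitched series is the source restricted to the window", {
  st <- tracking_example_store()
  # second plant that never moves
  assert_class(st, "plantX", "Plant")
  add_triple(st, "plantX", "locatedIn", "inst1")
  ss <- stitch(st, "plantX", "var:air_temperature", c("2017-05-01", "2017-05-03"))
  src <- st$series[st$series$sensor == "sA" &
    st$series$timestamp >= UTC("2017-05-01") &
    st$series$timestamp < UTC("2017-05-03"), ]
  expect_equal(ss$timestamp, src$timestamp)
  expect_equal(ss$value, src$value)
  expect_true(all(ss$location == "inst1"))
})

test_that("locations without an assigned sensor become gaps", {
  st <- pheno_store()
  v <- "var:temp"
  assert_class(st, c("inst1", "inst2", "p"), c("Installation", "Installation", "Plant"))
  add_triple(st, "p", "locatedIn", "inst1")
  record_event(st, "MoveTo", "2017-05-01", "p",
    properties = list(from_location = "inst1", to_location = "inst2")
  )
  assign_sensor(st, "inst1", v, "sA", "2017-04-01", NA)
  add_sensor_series(st, "sA", v, data.frame(
    timestamp = seq(UTC("2017-04-20"), UTC("2017-05-10"), by = 3600), value = 20
  ))
  ss <- stitch(st, "p", v, c("2017-04-20", "2017-05-10"))
  gaps <- attr(ss, "gaps")
  expect_equal(nrow(gaps), 1L)
  expect_equal(gaps$location, "inst2")
  expect_equal(gaps$reason, "no sensor")
  expect_equal(gaps$start, UTC("2017-05-01"))
  expect_true(all(ss$timestamp < UTC("2017-05-01")))
  expect_error(stitch(st, "ghost", v, c("2017-04-20", "2017-05-10")), "no placement")
})

test_that("stitched points conserve counts and carry verifiable provenance", {
  for (seed in 1:25) {
    sc <- random_schedule_store(seed)
    st <- sc$store
    v <- "var:temp"
    withr::with_seed(seed * 1000 + 1, {
      locs <- unique(st$classes$resource[st$classes$class == "Installation"])
      total_src <- 0
      for (loc in locs) {
        # each location gets 0-2 abutting assignment spans with its own sensor
        n_span <- sample(0:2, 1)
        if (n_span == 0) next
        cut <- UTC("2020-01-01") + sort(sample(1:59, n_span + 1)) * 86400
        for (j in seq_len(n_span)) {
          s <- paste0("sensor_", loc, "_", j)
          assign_sensor(st, loc, v, s, cut[j], cut[j + 1])
          ts <- seq(UTC("2020-01-01"), UTC("2020-03-01") - 1,
            by = sample(c(3600, 7200, 10800), 1)
          )
          add_sensor_series(st, s, v, data.frame(
            timestamp = ts, value = round(stats::rnorm(length(ts), 20, 5), 3)
          ))
        }
      }
    })
    iv <- residence_intervals(st, "obj", UTC("2020-01-01"), UTC("2020-03-01"))
    ss <- stitch(st, "obj", v, c(UTC("2020-01-01"), UTC("2020-03-01")))
    # conservation: served + lost = all in-interval points of location sensors
    a <- st$assignments
    total_src <- 0
    for (i in seq_len(nrow(iv))) {
      sensors_here <- a$sensor[a$location == iv$location[i] & a$variable == v]
      total_src <- total_src + sum(
        st$series$sensor %in% sensors_here &
          st$series$timestamp >= iv$start[i] & st$series$timestamp < iv$end[i]
      )
    }
    expect_equal(nrow(ss) + attr(ss, "lost_points"), total_src,
      label = paste("seed", seed)
    )
    # provenance: every point lies in its sensor's span and its interval
    if (nrow(ss)) {
      ok_interval <- ss$timestamp >= ss$interval_start & ss$timestamp < ss$interval_end
      ok_span <- vapply(seq_len(nrow(ss)), function(i) {
        sp <- a[a$sensor == ss$sensor[i] & a$location == ss$location[i], ]
        any(ss$timestamp[i] >= sp$start &
          (is.na(sp$end) | ss$timestamp[i] < sp$end))
      }, logical(1))
      expect_true(all(ok_interval) && all(ok_span), label = paste("seed", seed))
    }
  }
})

test_that("thermal time reproduces the constant-temperature closed form", {
  st <- pheno_store()
  v <- "var:temp"
  assert_class(st, c("inst1", "p"), c("Installation", "Plant"))
  add_triple(st, "p", "locatedIn", "inst1")
  record_event(st, "Sowing", "2017-04-13", "p", properties = list(location = "inst1"))
  assign_sensor(st, "inst1", v, "sA", "2017-04-13", NA)
  hrs <- seq(UTC("2017-04-13"), UTC("2017-04-18") - 1, by = 3600)
  add_sensor_series(st, "sA", v, data.frame(timestamp = hrs, value = 25))
  tt <- thermal_time(st, "p", v, base_temp = 10)
  expect_equal(nrow(tt), 5L)
  expect_equal(tt$increment, rep(15, 5))
  expect_equal(tt$thermal_time[5], 75) # (25 - 10) x 5 days
  expect_false(any(tt$no_data))
  # temperatures at or below base accumulate nothing
  tt0 <- thermal_time(st, "p", v, base_temp = 30)
  expect_true(all(tt0$thermal_time == 0))
  expect_error(thermal_time(st, "p", v), "base_temp")
})

test_that("thermal time follows the stitched series across a move", {
  st <- pheno_store()
  v <- "var:temp"
  assert_class(st, c("i1", "i2", "p"), c("Installation", "Installation", "Plant"))
  add_triple(st, "p", "locatedIn", "i1")
  record_event(st, "Sowing", "2017-04-13", "p", properties = list(location = "i1"))
  record_event(st, "MoveTo", "2017-04-14", "p",
    properties = list(from_location = "i1", to_location = "i2")
  )
  assign_sensor(st, "i1", v, "s1", "2017-04-13", NA)
  assign_sensor(st, "i2", v, "s2", "2017-04-13", NA)
  hrs <- seq(UTC("2017-04-13"), UTC("2017-04-16") - 1, by = 3600)
  add_sensor_series(st, "s1", v, data.frame(timestamp = hrs, value = 20))
  add_sensor_series(st, "s2", v, data.frame(timestamp = hrs, value = 30))
  tt <- thermal_time(st, "p", v, base_temp = 10)
  # day 1 in i1 (20 deg), days 2-3 in i2 (30 deg): 10 + 20 + 20
  expect_equal(tt$increment, c(10, 20, 20))
  expect_equal(tt$thermal_time, c(10, 30, 50))
})

test_that("days without data are flagged and contribute zero", {
  st <- pheno_store()
  v <- "var:temp"
  assert_class(st, c("i1", "p"), c("Installation", "Plant"))
  add_triple(st, "p", "locatedIn", "i1")
  record_event(st, "Sowing", "2017-04-13", "p", properties = list(location = "i1"))
  assign_sensor(st, "i1", v, "s1", "2017-04-13", NA)
  hrs <- c(
    seq(UTC("2017-04-13"), UTC("2017-04-14") - 1, by = 3600),
    seq(UTC("2017-04-15"), UTC("2017-04-16") - 1, by = 3600)
  )
  add_sensor_series(st, "s1", v, data.frame(timestamp = hrs, value = 25))
  tt <- thermal_time(st, "p", v, base_temp = 10, window_end = "2017-04-16")
  expect_equal(tt$no_data, c(FALSE, TRUE, FALSE))
  expect_equal(tt$increment, c(15, 0, 15))
  expect_true(all(diff(tt$thermal_time) >= 0))
})

test_that("thermal time is monotone on fluctuating simulated series", {
  st <- simulate_experiment(small_config(seed = 4))
  for (p in st$truth$plants[1:4]) {
    tt <- thermal_time(st, p, sim_variable("air_temperature"), base_temp = 10)
    expect_true(all(diff(tt$thermal_time) >= 0), label = p)
    expect_equal(attr(tt, "method"), "daily_mean_above_base")
  }
})

test_that("alternative thermal-time methods are registerable", {
  register_thermal_time_method("max_above_base", function(values, base_temp) {
    max(0, max(values) - base_temp)
  })
  expect_true("max_above_base" %in% thermal_time_methods())
  st <- pheno_store()
  v <- "var:temp"
  assert_class(st, c("i1", "p"), c("Installation", "Plant"))
  add_triple(st, "p", "locatedIn", "i1")
  record_event(st, "Sowing", "2017-04-13", "p", properties = list(location = "i1"))
  assign_sensor(st, "i1", v, "s1", "2017-04-13", NA)
  add_sensor_series(st, "s1", v, data.frame(
    timestamp = UTC(c("2017-04-13 06:00:00", "2017-04-13 15:00:00")),
    value = c(20, 30)
  ))
  tt <- thermal_time(st, "p", v, base_temp = 10, method = "max_above_base")
  expect_equal(tt$increment[1], 20)
  expect_equal(attr(tt, "method"), "max_above_base")
})
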