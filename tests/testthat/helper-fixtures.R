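# Shared fixtures, built in code.

UTC <- function(x) as.POSIXct(x, tz = "UTC")

# The two-installation tracking scenario: a plant placed in installation 1 on
# 13 April, moved to installation 2 on 19 May, moved back on 29 May, with
# constant-temperature sensors (20 degrees in 1, 30 in 2) recording hourly.
tracking_example_store <- function(temp1 = 20, temp2 = 30) {
  st <- pheno_store()
  assert_class(
    st, c("inst1", "inst2", "plant262", "sA", "sB"),
    c("Installation", "Installation", "Plant", "Sensor", "Sensor")
  )
  add_triple(st, "plant262", "locatedIn", "inst1")
  record_event(st, "Sowing", "2017-04-13", "plant262",
    properties = list(location = "inst1")
  )
  record_event(st, "MoveTo", "2017-05-19", "plant262",
    uri = "event:move_out",
    properties = list(from_location = "inst1", to_location = "inst2")
  )
  record_event(st, "MoveTo", "2017-05-29", "plant262",
    uri = "event:move_back",
    properties = list(from_location = "inst2", to_location = "inst1")
  )
  v <- "var:air_temperature"
  assign_sensor(st, "inst1", v, "sA", "2017-04-13", NA)
  assign_sensor(st, "inst2", v, "sB", "2017-04-13", NA)
  hrs <- seq(UTC("2017-04-13"), UTC("2017-06-02") - 1, by = 3600)
  add_sensor_series(st, "sA", v, data.frame(timestamp = hrs, value = temp1))
  add_sensor_series(st, "sB", v, data.frame(timestamp = hrs, value = temp2))
  st
}

# A field fixture: two plots with three leaves each and an image per plot;
# plot1 suffered a lodging incident.
lodging_store <- function() {
  st <- pheno_store()
  assert_class(st, c("plot1", "plot2"), "Plot")
  for (p in c("plot1", "plot2")) {
    leaves <- paste0(p, "_leaf", 1:3)
    assert_class(st, leaves, "Leaf")
    for (l in leaves) add_triple(st, l, "isPartOf", p)
    img <- paste0("img_", p)
    assert_class(st, img, "Image")
    add_triple(st, img, "concerns", p)
  }
  assert_class(st, "agent1", "Agent")
  record_event(st, "Incident", "2017-05-20", "plot1",
    uri = "event:lodging",
    agent = "agent1", description = "Plots lodged after the storm"
  )
  st
}

# Random part-of DAG over n nodes: each node gets 0-2 edges towards
# lower-numbered nodes, so the edge relation is acyclic by construction.
random_partof_dag <- function(n, seed) {
  withr::with_seed(seed, {
    edges <- list()
    for (i in 2:n) {
      k <- sample(0:2, 1)
      if (k > 0) {
        to <- sample(seq_len(i - 1), min(k, i - 1))
        edges[[length(edges) + 1]] <- data.frame(
          subject = paste0("n", i), predicate = "isPartOf",
          object = paste0("n", to)
        )
      }
    }
    if (!length(edges)) { # degenerate draw: keep at least one edge
      edges <- list(data.frame(
        subject = "n2", predicate = "isPartOf", object = "n1"
      ))
    }
    do.call(rbind, edges)
  })
}

# Independent reachability oracle for the closure: igraph BFS over the
# asserted edges; inferred pairs are reachable pairs that are not edges.
closure_oracle <- function(edges) {
  nodes <- unique(c(edges$subject, edges$object))
  g <- igraph::graph_from_data_frame(edges[, c("subject", "object")],
    directed = TRUE, vertices = nodes
  )
  d <- igraph::distances(g, mode = "out")
  pairs <- which(is.finite(d) & d > 0, arr.ind = TRUE)
  out <- data.frame(
    subject = rownames(d)[pairs[, 1]],
    object = colnames(d)[pairs[, 2]],
    stringsAsFactors = FALSE
  )
  asserted <- paste(edges$subject, edges$object)
  out <- out[!(paste(out$subject, out$object) %in% asserted), ]
  sort(paste(out$subject, out$object))
}

# Random valid move schedule for one object: placement at the window start,
# k moves at distinct instants through a chain of locations, optionally a
# harvest. Returns the store plus the expected partition end.
random_schedule_store <- function(seed, window_start = UTC("2020-01-01"),
                                  window_end = UTC("2020-03-01")) {
  withr::with_seed(seed, {
    st <- pheno_store()
    n_loc <- sample(2:5, 1)
    locs <- paste0("loc", seq_len(n_loc))
    assert_class(st, c(locs, "obj"), c(rep("Installation", n_loc), "Plant"))
    add_triple(st, "obj", "locatedIn", locs[1])
    span <- as.numeric(difftime(window_end, window_start, units = "secs"))
    k <- sample(0:6, 1)
    times <- sort(sample(seq(3600, span - 3600, by = 3600), k))
    cur <- locs[1]
    for (t in times) {
      nxt <- sample(setdiff(locs, cur), 1)
      record_event(st, "MoveTo", window_start + t, "obj", properties = list(
        from_location = cur, to_location = nxt
      ))
      cur <- nxt
    }
    harvest <- sample(c(TRUE, FALSE), 1)
    end_expected <- window_end
    if (harvest) {
      ht <- window_start + span - sample(1:20, 1) * 3600
      if (ht > window_start + max(c(0, times))) { # harvest after the last move
        record_event(st, "Harvest", ht, "obj")
        end_expected <- ht
      }
    }
    list(store = st, end = end_expected, n_moves = k)
  })
}

# Small, fast generator configuration for tests that only need structure.
small_config <- function(seed = 1, ...) {
  fixture_config(
    seed = seed, n_genotypes = 5, replicates_per_genotype = 4,
    sensor_cadence_hours = 6, obs_cadence_days = 5,
    move_fraction = 0.2, anomaly_fraction = 0.2, lodging_fraction = 0.4,
    ...
  )
}
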