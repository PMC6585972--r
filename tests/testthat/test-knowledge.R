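test_that("triple addition has set semantics and validates input", {
  st <- pheno_store()
  add_triple(st, "plant736", "participatesIn", "ExperimentA")
  add_triple(st, "plant736", "participatesIn", "ExperimentA")
  expect_equal(nrow(st$triples), 1L)
  expect_false(remove_triple(st, "plant736", "participatesIn", "ExperimentB"))
  expect_equal(nrow(st$triples), 1L)
  expect_true(remove_triple(st, "plant736", "participatesIn", "ExperimentA"))
  expect_equal(nrow(st$triples), 0L)
  expect_error(add_triple(st, "plant736", "", "x"), "non-empty")
  expect_error(add_triple(st, "s", "p", "x", literal_kind = "date"), "literal kind")
  expect_warning(add_triple(st, "s", "newPred", "x"), "auto-registering")
  expect_false(st$predicates$transitive[st$predicates$predicate == "newPred"])
})

test_that("subsumption is reflexive, transitive, and tree-shaped", {
  st <- pheno_store()
  expect_true(is_a(st, "Breakdown", "Trouble"))
  expect_true(is_a(st, "Breakdown", "Event"))
  expect_true(is_a(st, "Breakdown", "Breakdown"))
  expect_false(is_a(st, "Plant", "Trouble"))
  expect_error(is_a(st, "NoSuchClass", "Event"), "unknown class")
  expect_silent(phenotrack:::validate_hierarchy(builtin_hierarchy()))
  add_class(st, "SoilSensor", parent = "Sensor")
  expect_true(is_a(st, "SoilSensor", "Device"))
  expect_error(add_class(st, "SoilSensor", "Sensor"), "already registered")
})

test_that("transitive closure infers exactly multi-step part-of links", {
  st <- pheno_store()
  add_triple(st, "leaf884", "isPartOf", "plant736")
  add_triple(st, "plant736", "isPartOf", "plot12")
  cl <- kg_closure(st, "isPartOf")
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$subject, "leaf884")
  expect_equal(cl$object, "plot12")
  expect_error(kg_closure(st, "participatesIn"), "not flagged transitive")
  expect_equal(nrow(kg_closure(pheno_store(), "isPartOf")), 0L)
})

test_that("closure matches an independent BFS oracle on random DAGs", {
  skip_if_not_installed("igraph")
  for (seed in 1:40) {
    n <- 5 + (seed %% 20)
    edges <- random_partof_dag(n, seed)
    st <- pheno_store()
    add_triples(st, edges)
    got <- kg_closure(st, "isPartOf")
    expect_equal(sort(paste(got$subject, got$object)), closure_oracle(edges),
      label = paste("dag seed", seed)
    )
  }
})

test_that("closure is idempotent and introduces no new resources", {
  for (seed in c(3, 17, 42)) {
    edges <- random_partof_dag(15, seed)
    st <- pheno_store()
    add_triples(st, edges)
    inferred <- kg_closure(st, "isPartOf")
    before <- unique(c(st$triples$subject, st$triples$object))
    expect_true(all(c(inferred$subject, inferred$object) %in% before))
    add_triples(st, inferred)
    expect_equal(nrow(kg_closure(st, "isPartOf")), 0L)
  }
})

test_that("predicate paths retrieve across transitive and plain steps", {
  st <- pheno_store()
  add_triple(st, "sample331", "isPartOf", "plant736")
  add_triple(st, "plant736", "participatesIn", "ExperimentA")
  add_triple(st, "plant736", "hasVariety", "varietyA")
  expect_equal(
    kg_related(st, "sample331", c("isPartOf", "participatesIn")),
    "ExperimentA"
  )
  # a non-transitive step does not jump through part-of: no direct assertion
  expect_equal(kg_related(st, "sample331", "hasVariety"), character())
  expect_equal(kg_related(st, "nowhere", "isPartOf"), character())
  # inverse steps
  expect_equal(kg_related(st, "ExperimentA", "^participatesIn"), "plant736")
})

test_that("related over a part-of chain returns all ancestors (oracle walk)", {
  for (seed in c(5, 9)) {
    edges <- random_partof_dag(12, seed)
    st <- pheno_store()
    add_triples(st, edges)
    parent_map <- split(edges$object, edges$subject)
    walk_up <- function(x) {
      out <- character()
      frontier <- x
      while (length(frontier)) {
        nxt <- unique(unlist(parent_map[frontier], use.names = FALSE))
        nxt <- setdiff(nxt, out)
        out <- c(out, nxt)
        frontier <- nxt
      }
      sort(out)
    }
    for (x in unique(edges$subject)) {
      expect_equal(kg_related(st, x, "isPartOf"), walk_up(x), label = x)
    }
  }
})

test_that("instances_of honours subsumption", {
  st <- pheno_store()
  plants <- paste0("plant", 1:10)
  assert_class(st, plants, "Plant")
  assert_class(st, "event1", "Breakdown")
  expect_equal(instances_of(st, "Plant", FALSE), sort(plants))
  expect_true("event1" %in% instances_of(st, "Trouble", TRUE))
  expect_false("event1" %in% instances_of(st, "Trouble", FALSE))
  expect_equal(instances_of(pheno_store(), "Plant"), character())
  expect_error(instances_of(st, "Gizmo"), "unknown class")
})

test_that("N-Triples and Turtle serializations round-trip", {
  st <- simulate_experiment(small_config(seed = 2))
  for (fmt in c("ntriples", "turtle")) {
    path <- withr::local_tempfile(fileext = ".rdf")
    write_triples(st, path, format = fmt)
    st2 <- pheno_store()
    read_triples(st2, path, format = fmt)
    expect_equal(
      dplyr::arrange(st$triples, subject, predicate, object),
      dplyr::arrange(st2$triples, subject, predicate, object),
      label = fmt
    )
    expect_equal(
      dplyr::arrange(st$classes, resource, class),
      dplyr::arrange(st2$classes, resource, class),
      label = fmt
    )
  }
})

test_that("a Turtle statement with prefixed names expands to one triple", {
  st <- pheno_store()
  read_triples(st,
    text = c(
      "@prefix m3p: <http://www.phenome-fppn.fr/m3p/> .",
      "@prefix oepo: <http://www.phenome-fppn.fr/vocabulary/2018/oepo#> .",
      "m3p:arch/2017/c17000118 oepo:isPartOf m3p:arch/2013/pc13001542 ."
    ),
    format = "turtle"
  )
  expect_equal(nrow(st$triples), 1L)
  expect_equal(st$triples$subject, "http://www.phenome-fppn.fr/m3p/arch/2017/c17000118")
  expect_equal(st$triples$predicate, "isPartOf")
  expect_equal(st$triples$object, "http://www.phenome-fppn.fr/m3p/arch/2013/pc13001542")
})

test_that("syntax errors name the offending line", {
  st <- pheno_store()
  expect_error(
    read_triples(st,
      text = c("<a> <b> <c> .", "<a> <b> <c>"),
      format = "ntriples"
    ),
    "line 2"
  )
  expect_error(
    read_triples(st, text = "@prefix broken <x> .", format = "turtle"),
    "line 1"
  )
})

test_that("literals survive serialization with their kinds", {
  st <- pheno_store()
  add_triple(st, "plant1", "label", "a \"quoted\"\nlabel", literal_kind = "string")
  suppressWarnings({ # massGrams/sownAt auto-register as ad-hoc predicates
    add_triple(st, "plant1", "massGrams", "12.5", literal_kind = "number")
    add_triple(st, "plant1", "sownAt", "2017-04-13T00:00:00Z", literal_kind = "timestamp")
  })
  path <- withr::local_tempfile()
  write_triples(st, path)
  st2 <- pheno_store()
  suppressWarnings(read_triples(st2, path))
  expect_equal(
    dplyr::arrange(st$triples, predicate),
    dplyr::arrange(st2$triples, predicate)
  )
})
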