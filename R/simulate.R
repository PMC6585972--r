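#' Configuration of a synthetic experiment
#'
#' Describes the two worked installation types the generator emulates: a
#' glasshouse with individually potted, carted and imaged plants that can be
#' moved between two compartments with different climates, and a field with
#' genotype plots, tagged leaves, plot images and a meteorological station.
#' Defaults follow the study conditions: 59 genotypes with 4 glasshouse
#' replicates each, a campaign from 13 April to 2 June 2017
#' (50 days), moved plants spending 10 days in the second installation,
#' hourly temperature records and daily growth observations.
#'
#' @param seed integer; fixes all randomness. Per-resource random streams are
#'   derived by hashing the resource URI together with the seed, so adding a
#'   plant never perturbs another plant's data.
#' @param n_genotypes number of genotypes.
#' @param replicates_per_genotype glasshouse replicates per genotype.
#' @param start,end campaign dates (ISO-8601).
#' @param installations list of installation descriptors: `name`,
#'   `infrastructure` (a base abbreviation), `type` (`"glasshouse"` or
#'   `"field"`), and the diurnal temperature regime `mean_temp`, `amplitude`,
#'   `noise_sd` (degrees Celsius). The first glasshouse installation hosts the
#'   plants; moved plants visit the second.
#' @param move_fraction fraction of plants temporarily moved.
#' @param move_window days after sowing within which departures happen.
#' @param stay_days length of the stay in the second installation.
#' @param anomaly_fraction fraction of plants whose growth is contaminated.
#' @param growth_scale multiplicative factor applied to a contaminated plant's
#'   asymptotic size.
#' @param lodging_fraction fraction of field plots lodged.
#' @param lodging_date date of the lodging incident.
#' @param sensor_cadence_hours temperature sampling cadence.
#' @param obs_cadence_days growth observation cadence.
#' @return a `fixture_config` list.
#' @export
fixture_config <- function(seed = 1L,
                           n_genotypes = 59L,
                           replicates_per_genotype = 4L,
                           start = "2017-04-13",
                           end = "2017-06-02",
                           installations = list(
                             list(
                               name = "installation1", infrastructure = "m3p",
                               type = "glasshouse", mean_temp = 22, amplitude = 6,
                               noise_sd = 0.5
                             ),
                             list(
                               name = "installation2", infrastructure = "m3p",
                               type = "glasshouse", mean_temp = 28, amplitude = 4,
                               noise_sd = 0.5
                             ),
                             list(
                               name = "field1", infrastructure = "diaphen",
                               type = "field", mean_temp = 20, amplitude = 8,
                               noise_sd = 1
                             )
                           ),
                           move_fraction = 0.1,
                           move_window = c(20, 35),
                           stay_days = 10,
                           anomaly_fraction = 0.05,
                           growth_scale = 0.4,
                           lodging_fraction = 0.1,
                           lodging_date = "2017-05-20",
                           sensor_cadence_hours = 1,
                           obs_cadence_days = 1) {
  cfg <- list(
    seed = as.integer(seed), n_genotypes = as.integer(n_genotypes),
    replicates_per_genotype = as.integer(replicates_per_genotype),
    start = start, end = end, installations = installations,
    move_fraction = move_fraction, move_window = move_window,
    stay_days = stay_days, anomaly_fraction = anomaly_fraction,
    growth_scale = growth_scale, lodging_fraction = lodging_fraction,
    lodging_date = lodging_date, sensor_cadence_hours = sensor_cadence_hours,
    obs_cadence_days = obs_cadence_days
  )
  fr <- c(cfg$move_fraction, cfg$anomaly_fraction, cfg$lodging_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]", call. = FALSE)
  if (!(parse_instant(cfg$start) < parse_instant(cfg$end))) {
    stop("experiment span must be positive", call. = FALSE)
  }
  if (cfg$n_genotypes < 1 || cfg$replicates_per_genotype < 1) {
    stop("need at least one genotype and one replicate", call. = FALSE)
  }
  glass <- vapply(installations, function(x) identical(x$type, "glasshouse"), logical(1))
  if (sum(glass) < 1) stop("need at least one glasshouse installation", call. = FALSE)
  if (cfg$move_fraction > 0 && sum(glass) < 2) {
    stop("moving plants requires two glasshouse installations", call. = FALSE)
  }
  class(cfg) <- "fixture_config"
  cfg
}

#' Variable URIs used by the generator
#'
#' @param name short variable name (e.g. `"leaf_area"`).
#' @return the variable URI.
#' @export
sim_variable <- function(name) {
  paste0("http://www.phenome-fppn.fr/m3p/variable#", name)
}

logistic_curve <- function(day, l_max, rate, midpoint) {
  l_max / (1 + exp(-rate * (day - midpoint)))
}

diurnal_temperature <- function(ts, mean_temp, amplitude, noise_sd) {
  hour <- lubridate::hour(ts) + lubridate::minute(ts) / 60
  mean_temp + amplitude * sin(2 * pi * (hour - 9) / 24) +
    stats::rnorm(length(ts), 0, noise_sd)
}

#' Simulate a complete phenotyping experiment
#'
#' Deterministically (for a fixed seed) populates a store with the full object
#' web of a glasshouse + field campaign: infrastructures and installations,
#' minted URIs for plants, pots, carts, plots, leaves, sensors and images,
#' genotype and seed-lot provenance, trait-method-unit variables with external
#' ontology mappings, sowing/move/harvest events, a lodging incident on
#' selected plots, diurnal temperature series per installation (with a
#' mid-campaign sensor replacement in the first one), logistic growth curves
#' per plant (contaminated replicates scaled down) and plant-height and NDVI
#' observations.
#'
#' The planted structure is kept in `store$truth` (moved plants with their
#' departure/return instants, contaminated plants, lodged plots) so recovery
#' can be verified.
#'
#' @param config a [fixture_config()].
#' @return a populated [pheno_store()].
#' @export
simulate_experiment <- function(config = fixture_config()) {
  if (!inherits(config, "fixture_config")) {
    stop("`config` must come from fixture_config()", call. = FALSE)
  }
  st <- pheno_store()
  start <- parse_instant(config$start)
  end <- parse_instant(config$end)
  year <- lubridate::year(start)
  seed <- config$seed

  # --- infrastructure -----------------------------------------------------
  national <- "http://www.phenome-fppn.fr"
  assert_class(st, national, "NationalInfrastructure")
  for (b in st$config$bases) {
    assert_class(st, b, "LocalInfrastructure")
    add_triple(st, b, "isPartOf", national)
  }
  inst_uri <- function(inst) {
    paste0(expand_base(st$config, inst$infrastructure), "/", inst$name)
  }
  for (inst in config$installations) {
    u <- inst_uri(inst)
    assert_class(st, u, "Installation")
    add_triple(st, u, "isPartOf", expand_base(st$config, inst$infrastructure))
  }
  glasshouse <- Filter(function(x) x$type == "glasshouse", config$installations)
  fields <- Filter(function(x) x$type == "field", config$installations)
  home <- inst_uri(glasshouse[[1]])
  away <- if (length(glasshouse) > 1) inst_uri(glasshouse[[2]]) else NULL

  exp_glass <- paste0(st$config$bases[["m3p"]], "/", year, "/ExperimentA")
  assert_class(st, exp_glass, "Experiment")
  exp_field <- if (length(fields)) {
    u <- paste0(st$config$bases[["diaphen"]], "/", year, "/ExperimentB")
    assert_class(st, u, "Experiment")
    u
  } else {
    NULL
  }
  agent <- paste0(national, "/agents/user1")
  assert_class(st, agent, "Agent")

  # --- variables ----------------------------------------------------------
  term <- function(name, label, kind) {
    u <- paste0(national, "/term/", name)
    define_term(st, u, label, kind)
    u
  }
  tr_temp <- term("air_temperature", "air temperature", "trait")
  tr_la <- term("leaf_area", "leaf area", "trait")
  tr_h <- term("plant_height", "plant height", "trait")
  tr_ndvi <- term("ndvi", "canopy normalized difference vegetation index", "trait")
  tr_silk <- term("silk_volume", "Silk_volume", "trait")
  me_sensor <- term("sensor_record", "direct sensor record", "method")
  me_img3d <- term("image_analysis_3d", "3-D reconstruction image analysis", "method")
  me_pixel <- term("highest_green_pixel", "highest green pixel", "method")
  me_spectro <- term("spectrometry", "canopy spectrometry", "method")
  me_ear <- term("ear_image_local", "local maize ear image analysis", "method")
  un_c <- term("degree_celsius", "degree Celsius", "unit")
  un_m2 <- term("square_metre", "square metre", "unit")
  un_mm <- term("millimetre", "millimetre", "unit")
  un_idx <- term("index", "dimensionless index", "unit")
  un_px <- term("pixel", "pixel", "unit")
  define_variable(st, sim_variable("air_temperature"), tr_temp, me_sensor, un_c)
  define_variable(st, sim_variable("leaf_area"), tr_la, me_img3d, un_m2)
  define_variable(st, sim_variable("plant_height"), tr_h, me_pixel, un_mm)
  define_variable(st, sim_variable("ndvi"), tr_ndvi, me_spectro, un_idx)
  define_variable(st, sim_variable("silk_volume"), tr_silk, me_ear, un_px)
  add_mapping(st, tr_ndvi, "exactMatch", "CO_322:0000880")
  add_mapping(st, tr_silk, "closeMatch", "CO_322:0000144")
  add_mapping(st, tr_silk, "closeMatch", "CO_322:0000013")
  add_mapping(st, un_px, "exactMatch", "UO_0000242")
  v_temp <- sim_variable("air_temperature")

  # --- germplasm and seed lots ---------------------------------------------
  genotypes <- paste0(national, "/germplasm/variety", seq_len(config$n_genotypes))
  for (g in genotypes) assert_class(st, g, "Variety")
  lots <- paste0(national, "/seedlot/lot", seq_len(config$n_genotypes))
  for (l in lots) assert_class(st, l, "SeedLot")
  lot_contam <- paste0(national, "/seedlot/lot_contaminated")
  assert_class(st, lot_contam, "SeedLot")

  # --- sensors and temperature series --------------------------------------
  mid <- start + floor(as.numeric(difftime(end, start, units = "secs")) / 2)
  sensor_plan <- list()
  for (inst in config$installations) {
    loc <- inst_uri(inst)
    base <- inst$infrastructure
    if (identical(loc, home)) {
      s1 <- mint_uri(st, "ac", year, base = base, path = inst$name)$canonical
      s2 <- mint_uri(st, "ac", year, base = base, path = inst$name)$canonical
      assert_class(st, c(s1, s2), c("Sensor", "Sensor"))
      add_triples(st, tibble::tibble(
        subject = c(s1, s2), predicate = "measures", object = v_temp
      ))
      assign_sensor(st, loc, v_temp, s1, start, mid)
      assign_sensor(st, loc, v_temp, s2, mid, end)
      sensor_plan <- c(sensor_plan, list(
        list(sensor = s1, inst = inst, from = start, to = mid),
        list(sensor = s2, inst = inst, from = mid, to = end)
      ))
    } else {
      s <- mint_uri(st, "ac", year, base = base, path = inst$name)$canonical
      assert_class(st, s, "Sensor")
      add_triple(st, s, "measures", v_temp)
      assign_sensor(st, loc, v_temp, s, start, end)
      sensor_plan <- c(sensor_plan, list(
        list(sensor = s, inst = inst, from = start, to = end)
      ))
    }
  }
  for (sp in sensor_plan) {
    ts <- seq(sp$from, sp$to - 1, by = config$sensor_cadence_hours * 3600)
    vals <- withr::with_seed(
      derive_seed(seed, sp$sensor),
      diurnal_temperature(ts, sp$inst$mean_temp, sp$inst$amplitude, sp$inst$noise_sd)
    )
    add_sensor_series(st, sp$sensor, v_temp,
      tibble::tibble(timestamp = ts, value = vals),
      unit = "degree_celsius"
    )
  }

  # --- glasshouse plants ----------------------------------------------------
  n_plants <- config$n_genotypes * config$replicates_per_genotype
  plants <- character(n_plants)
  triple_rows <- vector("list", n_plants)
  k <- 0
  for (g in seq_len(config$n_genotypes)) {
    for (r in seq_len(config$replicates_per_genotype)) {
      k <- k + 1
      plant <- mint_uri(st, "c", year, base = "m3p", path = "arch")$canonical
      pot <- mint_uri(st, "pc", year, base = "m3p", path = "arch")$canonical
      cart <- mint_uri(st, "ct", year, base = "m3p", path = "arch")$canonical
      assert_class(st, c(pot, cart), c("Pot", "Cart"))
      plants[k] <- plant
      triple_rows[[k]] <- tibble::tibble(
        subject = c(plant, pot, plant, plant, plant),
        predicate = c("isPartOf", "isPartOf", "participatesIn", "hasVariety", "locatedIn"),
        object = c(pot, cart, exp_glass, genotypes[g], home)
      )
    }
  }
  plant_genotype <- rep(genotypes, each = config$replicates_per_genotype)

  # planted anomalies and move schedule (global selections)
  picks <- withr::with_seed(derive_seed(seed, "selection"), {
    list(
      contaminated = plants[stats::runif(n_plants) < config$anomaly_fraction],
      moved = plants[sample.int(n_plants, round(config$move_fraction * n_plants))],
      move_day = stats::runif(n_plants, config$move_window[1], config$move_window[2])
    )
  })
  contaminated <- picks$contaminated
  for (i in seq_len(n_plants)) {
    lot <- if (plants[i] %in% contaminated) lot_contam else lots[match(plant_genotype[i], genotypes)]
    triple_rows[[i]] <- dplyr::bind_rows(
      triple_rows[[i]],
      tibble::tibble(subject = plants[i], predicate = "derivesFrom", object = lot)
    )
  }
  add_triples(st, dplyr::bind_rows(triple_rows))

  for (p in plants) {
    record_event(st, "Sowing", start, p,
      properties = list(location = home)
    )
  }

  moves <- tibble::tibble(
    plant = character(), depart = empty_instant(), ret = empty_instant()
  )
  if (length(picks$moved) && !is.null(away)) {
    span_days <- as.numeric(difftime(end, start, units = "days"))
    for (p in picks$moved) {
      d0 <- min(picks$move_day[match(p, plants)], span_days - config$stay_days - 1)
      depart <- start + round(d0) * 86400
      ret <- depart + config$stay_days * 86400
      record_event(st, "MoveTo", depart, p, properties = list(
        from_location = home, to_location = away
      ))
      record_event(st, "MoveTo", ret, p, properties = list(
        from_location = away, to_location = home
      ))
      moves <- dplyr::bind_rows(moves, tibble::tibble(
        plant = p, depart = depart, ret = ret
      ))
    }
  }
  for (p in plants) record_event(st, "Harvest", end, p)

  # growth observations (leaf area, plant height): genotypes differ in their
  # logistic parameters; replicates of one genotype are near-clones with a
  # small multiplicative jitter (controlled conditions), so a contaminated
  # replicate (asymptote scaled by growth_scale) stands clearly apart from
  # its siblings, as in an expert replicate screen.
  obs_days <- seq(0, as.numeric(difftime(end, start, units = "days")) - 1,
    by = config$obs_cadence_days
  )
  geno_pars <- lapply(genotypes, function(g) {
    withr::with_seed(derive_seed(seed, g), list(
      l_max = max(0.2, stats::rnorm(1, 0.65, 0.08)),
      h_max = max(600, stats::rnorm(1, 1600, 150)),
      rate = max(0.08, stats::rnorm(1, 0.22, 0.02)),
      mid_day = stats::rnorm(1, 25, 2)
    ))
  })
  names(geno_pars) <- genotypes
  obs <- lapply(seq_len(n_plants), function(i) {
    p <- plants[i]
    gp <- geno_pars[[plant_genotype[i]]]
    withr::with_seed(derive_seed(seed, p), {
      jitter <- 1 + stats::rnorm(1, 0, 0.04)
      l_max <- gp$l_max * jitter
      h_max <- gp$h_max * jitter
      mid_day <- gp$mid_day + stats::rnorm(1, 0, 0.5)
      if (p %in% contaminated) {
        l_max <- l_max * config$growth_scale
        h_max <- h_max * config$growth_scale
      }
      la <- pmax(0, logistic_curve(obs_days, l_max, gp$rate, mid_day) +
        stats::rnorm(length(obs_days), 0, 0.005))
      h <- pmax(0, logistic_curve(obs_days, h_max, gp$rate, mid_day) +
        stats::rnorm(length(obs_days), 0, 10))
      tibble::tibble(
        object = p,
        variable = rep(c(sim_variable("leaf_area"), sim_variable("plant_height")),
          each = length(obs_days)
        ),
        timestamp = rep(start + obs_days * 86400 + 12 * 3600, 2),
        value = c(la, h)
      )
    })
  })
  add_observations(st, dplyr::bind_rows(obs))

  # --- field plots ----------------------------------------------------------
  lodged <- character()
  if (length(fields)) {
    field_loc <- inst_uri(fields[[1]])
    plots <- character(config$n_genotypes)
    plot_rows <- vector("list", config$n_genotypes)
    for (g in seq_len(config$n_genotypes)) {
      plot <- mint_uri(st, "o", year, base = "diaphen")$canonical
      plots[g] <- plot
      leaves <- vapply(1:3, function(j) {
        mint_uri(st, "l", year, base = "diaphen")$canonical
      }, character(1))
      image <- mint_uri(st, "ic", year, base = "diaphen")$canonical
      plot_rows[[g]] <- tibble::tibble(
        subject = c(plot, plot, plot, leaves, image),
        predicate = c(
          "participatesIn", "hasVariety", "locatedIn",
          rep("isPartOf", 3), "concerns"
        ),
        object = c(exp_field, genotypes[g], field_loc, rep(plot, 4))
      )
    }
    add_triples(st, dplyr::bind_rows(plot_rows))
    for (p in plots) {
      record_event(st, "Sowing", start, p, properties = list(location = field_loc))
    }
    # NDVI progression per plot
    ndvi <- lapply(seq_along(plots), function(g) {
      withr::with_seed(derive_seed(seed, plots[g]), {
        v <- pmin(0.95, pmax(
          0.05,
          logistic_curve(obs_days, stats::rnorm(1, 0.85, 0.05), 0.2, 20) +
            stats::rnorm(length(obs_days), 0, 0.01)
        ))
        tibble::tibble(
          object = plots[g], variable = sim_variable("ndvi"),
          timestamp = start + obs_days * 86400 + 12 * 3600, value = v
        )
      })
    })
    add_observations(st, dplyr::bind_rows(ndvi))
    n_lodged <- round(config$lodging_fraction * length(plots))
    if (n_lodged > 0) {
      lodged <- withr::with_seed(
        derive_seed(seed, "lodging"),
        sample(plots, n_lodged)
      )
      record_event(st, "Incident", parse_instant(config$lodging_date), lodged,
        agent = agent, description = "Plots lodged after the storm"
      )
    }
  }

  st$truth <- list(
    config = config, plants = plants, genotype = plant_genotype,
    moved = moves, contaminated = contaminated, lodged = lodged,
    home = home, away = away
  )
  st
}
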