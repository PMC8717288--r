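# Synthetic-forest generator: point processes, marks, environment.
#
# Every generator is a pure function of (parameters, seed); the same seed
# reproduces the same dataset exactly.

#' Homogeneous Poisson (CSR) point pattern in a transect window
#'
#' Counts per rectangle are Poisson(intensity x area); locations are uniform
#' within each rectangle.
#'
#' @param window a [transect_window].
#' @param intensity trees per hectare (> 0).
#' @param seed integer seed.
#' @return data frame `x`, `y`, `transect_id`.
#' @export
sim_poisson <- function(window, intensity, seed = NULL) {
  if (!is.numeric(intensity) || intensity <= 0) stop("intensity must be > 0")
  r <- window$rectangles
  with_seed(seed, {
    out <- vector("list", nrow(r))
    for (k in seq_len(nrow(r))) {
      a_ha <- (r$xmax[k] - r$xmin[k]) * (r$ymax[k] - r$ymin[k]) / 1e4
      n <- stats::rpois(1, intensity * a_ha)
      out[[k]] <- data.frame(
        x = stats::runif(n, r$xmin[k], r$xmax[k]),
        y = stats::runif(n, r$ymin[k], r$ymax[k]),
        transect_id = rep(r$transect_id[k], n), stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

#' Thomas cluster process in a transect window
#'
#' Parents form a Poisson process in each rectangle dilated by `4 * cluster_sd`
#' on every side (so clusters centred just outside still contribute offspring);
#' each parent gets a Poisson(`mean_offspring`) number of offspring displaced
#' by an isotropic Gaussian with standard deviation `cluster_sd`, and offspring
#' are clipped to the rectangle. Under this process the pair correlation
#' function is `g(r) = 1 + exp(-r^2 / (4 sd^2)) / (4 pi kappa sd^2)` with
#' `kappa` the parent intensity per m^2.
#'
#' @param window a [transect_window].
#' @param parent_intensity parents per hectare (> 0).
#' @param mean_offspring mean offspring per parent (>= 0).
#' @param cluster_sd Gaussian dispersal standard deviation, metres (> 0).
#' @param seed integer seed.
#' @return data frame `x`, `y`, `transect_id`; the realized parent locations
#'   are attached as attribute `parents` (data frame `x`, `y`, `transect_id`).
#' @export
sim_thomas <- function(window, parent_intensity, mean_offspring, cluster_sd,
                       seed = NULL) {
  if (parent_intensity <= 0 || cluster_sd <= 0 || mean_offspring < 0)
    stop("parent_intensity and cluster_sd must be > 0, mean_offspring >= 0")
  r <- window$rectangles
  m <- 4 * cluster_sd
  with_seed(seed, {
    pts <- vector("list", nrow(r)); par <- vector("list", nrow(r))
    for (k in seq_len(nrow(r))) {
      a_ha <- (r$xmax[k] - r$xmin[k] + 2 * m) * (r$ymax[k] - r$ymin[k] + 2 * m) / 1e4
      np <- stats::rpois(1, parent_intensity * a_ha)
      px <- stats::runif(np, r$xmin[k] - m, r$xmax[k] + m)
      py <- stats::runif(np, r$ymin[k] - m, r$ymax[k] + m)
      no <- if (np) stats::rpois(np, mean_offspring) else integer(0)
      ox <- rep(px, no) + stats::rnorm(sum(no), 0, cluster_sd)
      oy <- rep(py, no) + stats::rnorm(sum(no), 0, cluster_sd)
      keep <- ox >= r$xmin[k] & ox <= r$xmax[k] & oy >= r$ymin[k] & oy <= r$ymax[k]
      pts[[k]] <- data.frame(x = ox[keep], y = oy[keep],
                             transect_id = rep(r$transect_id[k], sum(keep)),
                             stringsAsFactors = FALSE)
      par[[k]] <- data.frame(x = px, y = py,
                             transect_id = rep(r$transect_id[k], np),
                             stringsAsFactors = FALSE)
    }
    structure(do.call(rbind, pts), parents = do.call(rbind, par))
  })
}

#' Inhomogeneous Poisson pattern tied to watercourses
#'
#' Thinning of a homogeneous Poisson pattern with retention probability
#' `exp(-dist_water / decay)`, where `dist_water` is the distance to the
#' nearest configured river line (vertical lines at fixed x positions). Used
#' for the water-affine shade-tolerant reference species.
#'
#' @param window a [transect_window].
#' @param intensity_max intensity at the river line, trees per hectare.
#' @param rivers_x numeric vector of river x positions (metres).
#' @param decay e-folding distance of the intensity, metres.
#' @param seed integer seed.
#' @return data frame `x`, `y`, `transect_id`.
#' @export
sim_water_affine <- function(window, intensity_max, rivers_x, decay, seed = NULL) {
  if (!length(rivers_x)) stop("no river positions configured")
  if (intensity_max <= 0 || decay <= 0) stop("intensity_max and decay must be > 0")
  with_seed(seed, {
    base <- sim_poisson(window, intensity_max, seed = NULL)
    d <- dist_to_rivers(base$x, rivers_x)
    base[stats::runif(nrow(base)) < exp(-d / decay), , drop = FALSE]
  })
}

dist_to_rivers <- function(x, rivers_x) {
  if (!length(rivers_x)) return(rep(Inf, length(x)))
  do.call(pmin, lapply(rivers_x, function(r) abs(x - r)))
}

#' Saturating (von Bertalanffy style) diameter growth curve
#'
#' `dbh(age) = dmax * (1 - exp(-k * age))`, cm. Only the cohort similarity of
#' same-patch stems matters for the autocorrelation tests; the curve just maps
#' patch age to a cohort mean diameter monotonically.
#'
#' @param age stand age in years.
#' @param dmax asymptotic diameter, cm.
#' @param k growth rate per year.
#' @export
vb_growth <- function(age, dmax = 150, k = 0.015) dmax * (1 - exp(-k * age))

#' Cohort-structured diameter marks
#'
#' Assigns each point to the nearest patch centre; the patch age sets the
#' cohort mean diameter through `growth`, and individual diameters are the
#' cohort mean plus Gaussian noise, floored at the 10 cm survey threshold.
#' Emulates even-aged cohorts that settled together in disturbance gaps.
#'
#' @param points data frame with `x`, `y`.
#' @param patch_centres data frame with `x`, `y` (one row per patch).
#' @param patch_ages numeric vector of patch ages (years), one per centre.
#' @param growth function age -> cm; default [vb_growth].
#' @param noise_sd within-cohort diameter standard deviation, cm.
#' @param seed integer seed.
#' @return numeric vector of dbh marks; patch index attached as attribute
#'   `patch`.
#' @export
assign_cohort_dbh <- function(points, patch_centres, patch_ages,
                              growth = vb_growth, noise_sd = 5, seed = NULL) {
  if (is.null(patch_centres) || nrow(patch_centres) == 0)
    stop("empty patch list")
  stopifnot(length(patch_ages) == nrow(patch_centres))
  d2 <- outer(points$x, patch_centres$x, "-")^2 +
    outer(points$y, patch_centres$y, "-")^2
  patch <- max.col(-d2, ties.method = "first")
  with_seed(seed, {
    dbh <- growth(patch_ages[patch]) + stats::rnorm(nrow(points), 0, noise_sd)
    structure(pmax(dbh, DBH_MIN), patch = patch)
  })
}

#' Synthetic subplot environment table
#'
#' Altitude along each transect is a linear gradient plus smooth sinusoidal
#' noise, optionally carved by Gaussian valleys centred on the river lines
#' (`valley_depth > 0` makes altitude and distance-to-water positively
#' correlated, as in a dissected landscape). Slope is the absolute altitude
#' gradient in percent; distance to water is the distance to the nearest
#' river line; topography is a deterministic function of the slope and of the
#' altitude quartiles: steep subplots are `slope`, the lowest quartile is
#' `shallow`, the highest `crest`, the rest `flat`.
#'
#' @param window a [transect_window].
#' @param rivers_x river x positions, metres.
#' @param altitude_base base altitude, m.
#' @param altitude_trend linear gradient along x, m per m.
#' @param noise_amp amplitudes of the sinusoidal terms, m.
#' @param noise_wavelength wavelengths of the sinusoidal terms, m.
#' @param valley_depth depth of the river valleys, m (0 = no valleys).
#' @param valley_width Gaussian half-width of the valleys, m.
#' @param slope_threshold slope (percent) above which topography = "slope".
#' @param seed integer seed (random phases of the sinusoids).
#' @return environment data frame (one row per 25 m x 50 m subplot) with the
#'   columns of [read_environment].
#' @export
gen_environment <- function(window, rivers_x = numeric(0),
                            altitude_base = 450, altitude_trend = 0.002,
                            noise_amp = c(3, 2), noise_wavelength = c(1300, 700),
                            valley_depth = 0, valley_width = 150,
                            slope_threshold = 8, seed = NULL) {
  stopifnot(length(noise_amp) == length(noise_wavelength))
  sub <- make_subplots(window)
  phase <- with_seed(seed, stats::runif(length(noise_amp), 0, 2 * pi))
  alt_fun <- function(x) {
    a <- altitude_base + altitude_trend * x
    for (i in seq_along(noise_amp))
      a <- a + noise_amp[i] * sin(2 * pi * x / noise_wavelength[i] + phase[i])
    if (valley_depth > 0 && length(rivers_x))
      for (r in rivers_x)
        a <- a - valley_depth * exp(-(x - r)^2 / (2 * valley_width^2))
    a
  }
  alt <- alt_fun(sub$cx)
  grad <- (alt_fun(sub$cx + 1) - alt_fun(sub$cx - 1)) / 2   # m per m
  slope_pct <- abs(grad) * 100
  q <- stats::quantile(alt, c(0.25, 0.75), names = FALSE)
  topo <- ifelse(slope_pct > slope_threshold, "slope",
                 ifelse(alt < q[1], "shallow",
                        ifelse(alt > q[2], "crest", "flat")))
  data.frame(
    subplot_id = sub$subplot_id, transect_id = sub$transect_id,
    cx = sub$cx, cy = sub$cy,
    slope_pct = slope_pct, topography = topo, altitude_m = alt,
    dist_water_m = dist_to_rivers(sub$cx, rivers_x),
    stringsAsFactors = FALSE
  )
}

#' Scenario configuration for the synthetic forest
#'
#' Bundles a window, a per-species process specification, an environment
#' specification and a seed. Each species entry is a list with fields
#' `guild`; `process` (`"poisson"`, `"thomas"` or `"water"`); process
#' parameters (`intensity` for poisson, `parent_intensity` / `mean_offspring`
#' / `cluster_sd` for thomas, `intensity_max` / `decay` for water); and
#' `marks`, either `list(model = "iid_lognormal", meanlog, sdlog)` or
#' `list(model = "cohort", age_range, noise_sd)`.
#'
#' @param window a [transect_window].
#' @param species named list of species specifications (names = codes).
#' @param env list of [gen_environment] arguments (without window/seed).
#' @param seed master integer seed; recorded in every output.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(window, species, env = list(), seed = 1) {
  stopifnot(inherits(window, "transect_window"), length(species) >= 1,
            !is.null(names(species)))
  structure(list(window = window, species = species, env = env, seed = seed),
            class = "scenario_config")
}

#' Preset scenarios for the three working hypotheses
#'
#' * `"h1"` (disturbance cohorts): the two short-lived pioneer species follow
#'   a Thomas cluster process and carry cohort-structured diameters (each
#'   cluster is an even-aged patch); other species are Poisson with iid marks.
#' * `"h2"` (random placement): every species is Poisson with iid lognormal
#'   diameters.
#' * `"h3"` (environmental filtering): as `"h2"`, but the shade-tolerant
#'   reference species is concentrated near the river lines.
#'
#' Process rates are per hectare, so the same preset can be realized in the
#' full 250.625 ha survey window or in a smaller desk-scale window.
#'
#' @param template `"h1"`, `"h2"` or `"h3"`.
#' @param window a [transect_window]; default the full survey geometry.
#' @param seed master seed.
#' @return a [scenario_config].
#' @export
scenario_preset <- function(template = c("h1", "h2", "h3"),
                            window = yangambi_window(), seed = 1) {
  template <- match.arg(template)
  maxlen <- max(window$rectangles$xmax)
  rivers <- seq(400, maxlen - 100, by = 800)
  iid <- function(mlog, slog) list(model = "iid_lognormal", meanlog = mlog, sdlog = slog)
  slp_thomas <- list(guild = "SLP", process = "thomas", parent_intensity = 0.15,
                     mean_offspring = 15, cluster_sd = 50,
                     marks = list(model = "cohort", age_range = c(20, 150), noise_sd = 5))
  slp_pois <- list(guild = "SLP", process = "poisson", intensity = 2.25,
                   marks = iid(log(25), 0.35))
  llp <- list(guild = "LLP", process = "poisson", intensity = 1.6,
              marks = iid(log(40), 0.30))
  npld <- list(guild = "NPLD", process = "poisson", intensity = 2.0,
               marks = iid(log(35), 0.35))
  sts_pois <- list(guild = "STS", process = "poisson", intensity = 2.0,
                   marks = iid(log(45), 0.40))
  sts_water <- list(guild = "STS", process = "water", intensity_max = 40,
                    decay = 40, marks = iid(log(45), 0.40))
  species <- switch(template,
    h1 = list(MUSCE = slp_thomas, MACMO = slp_thomas, PERIE = llp,
              PETER = npld, GILBE = sts_pois),
    h2 = list(MUSCE = slp_pois, MACMO = slp_pois, PERIE = llp,
              PETER = npld, GILBE = sts_pois),
    h3 = list(MUSCE = slp_pois, MACMO = slp_pois, PERIE = llp,
              PETER = npld, GILBE = sts_water))
  scenario_config(window, species,
                  env = list(rivers_x = rivers), seed = seed)
}

#' Generate a full synthetic community
#'
#' Realizes every species of a [scenario_config] in its window, attaches
#' diameter marks, builds the subplot environment table and records every
#' generative parameter in a truth list for recovery tests. Sub-seeds are
#' derived per species and stage from the master seed with [sub_seed].
#'
#' @param scenario a [scenario_config].
#' @return list with elements `stems` (a [stem_table]), `env` (environment
#'   data frame), `truth` (list of generative parameters, realized counts and
#'   the master seed).
#' @export
gen_community <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_config"))
  w <- scenario$window; seed <- scenario$seed
  env_args <- c(list(window = w), scenario$env,
                list(seed = sub_seed(seed, "environment")))
  env <- do.call(gen_environment, env_args)
  rivers <- scenario$env$rivers_x %||% numeric(0)
  rows <- list(); truth_sp <- list()
  for (code in names(scenario$species)) {
    sp <- scenario$species[[code]]
    pseed <- sub_seed(seed, "points", code)
    pts <- switch(sp$process,
      poisson = sim_poisson(w, sp$intensity, pseed),
      thomas = sim_thomas(w, sp$parent_intensity, sp$mean_offspring,
                          sp$cluster_sd, pseed),
      water = sim_water_affine(w, sp$intensity_max, rivers, sp$decay, pseed),
      stop("unknown process: ", sp$process))
    mseed <- sub_seed(seed, "marks", code)
    mk <- sp$marks
    patch_ages <- NULL
    if (nrow(pts) == 0) {
      dbh <- numeric(0)
    } else if (mk$model == "iid_lognormal") {
      dbh <- with_seed(mseed,
        pmax(stats::rlnorm(nrow(pts), mk$meanlog, mk$sdlog), DBH_MIN))
    } else if (mk$model == "cohort") {
      centres <- attr(pts, "parents")
      if (is.null(centres) || nrow(centres) == 0)
        stop("cohort marks need a clustered process with parents")
      patch_ages <- with_seed(sub_seed(seed, "ages", code),
        stats::runif(nrow(centres), mk$age_range[1], mk$age_range[2]))
      dbh <- assign_cohort_dbh(pts, centres, patch_ages,
                               noise_sd = mk$noise_sd, seed = mseed)
    } else stop("unknown mark model: ", mk$model)
    if (nrow(pts)) {
      rows[[code]] <- data.frame(
        tree_id = sprintf("%s_%05d", code, seq_len(nrow(pts))),
        transect_id = pts$transect_id, x = pts$x, y = pts$y,
        species = code, guild = sp$guild, dbh = as.numeric(dbh),
        stringsAsFactors = FALSE)
    }
    truth_sp[[code]] <- c(sp[setdiff(names(sp), "marks")],
                          list(marks = mk, n_realized = nrow(pts),
                               patch_ages = patch_ages))
  }
  stems_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tree_id = character(0), transect_id = character(0),
               x = numeric(0), y = numeric(0), species = character(0),
               guild = character(0), dbh = numeric(0))
  rownames(stems_df) <- NULL
  list(stems = stem_table(stems_df, w), env = env,
       truth = list(seed = seed, species = truth_sp, env = scenario$env,
                    window_area_ha = w$area_ha))
}
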