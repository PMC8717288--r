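# Study pipeline: orchestrates the full analysis sequence over one stem map —
# filtering, per-species and per-guild pair-correlation envelopes, Moran
# correlograms, intertype tests among short-lived pioneer pairs, and the
# four-way CCA (guild/species x with/without the reference species).

#' Configuration of a study run
#'
#' @param min_n minimum individuals per species for species-level analyses.
#' @param r_grid distances (m) for the pair correlation function.
#' @param bin_edges distance-class edges (m) for the Moran correlograms.
#' @param n_sim CSR simulations for the PCF envelope.
#' @param n_perm permutations for Moran envelopes, Mantel and CCA tests.
#' @param alpha two-sided envelope/test level.
#' @param reference_species code of the aggregated shade-tolerant reference
#'   species, removed in the "without" CCA blocks.
#' @param min_run minimum significant run length for pattern classification.
#' @param max_mantel_n largest unit size for which the (O(n^2) memory) Mantel
#'   summary test is computed; larger units report `NA`.
#' @param seed master seed; every stochastic stage derives its own sub-seed
#'   from it via [sub_seed], so results are reproducible and adding one unit
#'   does not shift the randomness of the others.
#' @return list of class `run_config`.
#' @export
run_config <- function(min_n = 50, r_grid = seq(10, 1000, by = 10),
                       bin_edges = seq(0, 4000, by = 100), n_sim = 100,
                       n_perm = 999, alpha = 0.05,
                       reference_species = "GILBE", min_run = 2,
                       max_mantel_n = 2000, seed = 1) {
  structure(list(min_n = min_n, r_grid = r_grid, bin_edges = bin_edges,
                 n_sim = n_sim, n_perm = n_perm, alpha = alpha,
                 reference_species = reference_species, min_run = min_run,
                 max_mantel_n = max_mantel_n, seed = seed),
            class = "run_config")
}

analyse_unit <- function(name, kind, pts, marks, window, cfg) {
  res <- list(unit = name, kind = kind, n = nrow(pts),
              density_ha = nrow(pts) / window_area_ha(window))
  res$pattern <- tryCatch({
    env <- csr_envelope(pts, window, cfg$r_grid, n_sim = cfg$n_sim,
                        alpha = cfg$alpha,
                        seed = sub_seed(cfg$seed, "pcf_envelope", name),
                        min_run = cfg$min_run)
    list(classification = env$classification, extent_m = env$extent_m,
         envelope = env)
  }, error = function(e) list(error = conditionMessage(e)))
  res$moran <- tryCatch({
    bins <- distance_bins(cfg$bin_edges)
    mantel_ok <- nrow(pts) <= cfg$max_mantel_n
    cg <- moran_correlogram(pts, marks, bins)
    env <- mark_permutation_envelope(pts, marks, bins, n_perm = cfg$n_perm,
                                     alpha = cfg$alpha,
                                     seed = sub_seed(cfg$seed, "moran", name))
    first <- which(!is.na(cg$I))[1]
    mt <- if (mantel_ok)
      dbh_mantel(pts, marks, n_perm = cfg$n_perm,
                 seed = sub_seed(cfg$seed, "mantel", name))
      else list(r = NA_real_, p = NA_real_)
    # the field convention interprets correlograms only for aggregated taxa;
    # computed for all units, flagged here
    list(correlogram = cbind(cg, env[, c("env_lo", "env_hi")]),
         short_range_positive = !is.na(cg$I[first]) &&
           cg$I[first] > env$env_hi[first],
         mantel_r = mt$r, mantel_p = mt$p,
         interpret = identical(res$pattern$classification, "aggregated"))
  }, error = function(e) list(error = conditionMessage(e)))
  res
}

cca_block <- function(label, Y, env_tab, cfg) {
  tryCatch({
    fit <- fit_cca(Y, env_tab)
    sel <- backward_select(Y, env_tab)
    list(label = label, fit = fit,
         proportion_constrained = fit$proportion_constrained,
         margin = anova_cca(fit, n_perm = cfg$n_perm,
                            seed = sub_seed(cfg$seed, "cca_margin", label),
                            scope = "margin"),
         model = anova_cca(fit, n_perm = cfg$n_perm,
                           seed = sub_seed(cfg$seed, "cca_model", label),
                           scope = "model"),
         decomposition = variance_decomposition(fit),
         selected_terms = sel$terms, selection_trace = sel$trace)
  }, error = function(e) list(label = label, error = conditionMessage(e)))
}

#' Run the full study workflow on one stem map
#'
#' Stages, in order: species filter; per-guild and per-species PCF with CSR
#' envelope and pattern classification; Moran correlograms of dbh with
#' permutation envelopes and Mantel summary (guild-level correlograms use
#' species-mean standardized diameters, species-level use raw dbh); intertype
#' Moran tests for every pair of retained short-lived pioneer species; CCA of
#' the subplot abundance matrices against the subplot environment, four ways
#' (guild/species x with/without the reference species). A failing stage is
#' recorded for its unit and the run continues.
#'
#' @param stems a [stem_table].
#' @param env subplot environment table (see [read_environment]).
#' @param window a [transect_window].
#' @param config a [run_config].
#' @param total_registered optional total tree count of the survey (all
#'   species) for the target-share summary.
#' @return object of class `study_report`.
#' @export
run_study <- function(stems, env, window, config = run_config(),
                      total_registered = NULL) {
  cfg <- config
  guilds_present <- intersect(GUILDS, unique(stems$guild))
  kept <- filter_species(stems, cfg$min_n)
  species <- attr(kept, "retained_species")
  std <- if (nrow(stems)) standardize_dbh_by_species(stems) else stems

  units <- list()
  for (g in guilds_present) {
    sub <- std[std$guild == g, , drop = FALSE]
    units[[paste0("guild_", g)]] <-
      analyse_unit(g, "guild", sub[, c("x", "y")], sub$dbh_std, window, cfg)
  }
  for (s in species) {
    sub <- kept[kept$species == s, , drop = FALSE]
    units[[paste0("species_", s)]] <-
      analyse_unit(s, "species", sub[, c("x", "y")], sub$dbh, window, cfg)
  }

  slp <- intersect(species, unique(stems$species[stems$guild == "SLP"]))
  intertype <- list()
  if (length(slp) >= 2) {
    for (a in seq_len(length(slp) - 1)) for (b in seq(a + 1, length(slp))) {
      s1 <- slp[a]; s2 <- slp[b]
      key <- paste(s1, s2, sep = "_x_")
      intertype[[key]] <- tryCatch({
        p1 <- kept[kept$species == s1, , drop = FALSE]
        p2 <- kept[kept$species == s2, , drop = FALSE]
        bins <- distance_bins(cfg$bin_edges)
        it <- intertype_moran(p1[, c("x", "y")], p1$dbh,
                              p2[, c("x", "y")], p2$dbh, bins)
        ite <- intertype_envelope(p1[, c("x", "y")], p1$dbh,
                                  p2[, c("x", "y")], p2$dbh, bins,
                                  n_perm = cfg$n_perm, alpha = cfg$alpha,
                                  seed = sub_seed(cfg$seed, "intertype", key))
        first <- which(!is.na(it$I12))[1]
        list(pair = c(s1, s2),
             correlogram = cbind(it, ite[, c("env_lo", "env_hi")]),
             short_range_positive = !is.na(it$I12[first]) &&
               it$I12[first] > ite$env_hi[first])
      }, error = function(e) list(pair = c(s1, s2),
                                  error = conditionMessage(e)))
    }
  }

  subplots <- make_subplots(window)
  cca <- list()
  ref <- cfg$reference_species
  Yg <- tabulate_abundance(stems, subplots, "guild")
  Ys <- tabulate_abundance(kept, subplots, "species")
  cca$guild_with <- cca_block("guild_with_reference", Yg, env, cfg)
  cca$species_with <- cca_block("species_with_reference", Ys, env, cfg)
  ref_guild <- unique(stems$guild[stems$species == ref])
  Yg0 <- tabulate_abundance(stems[stems$species != ref, , drop = FALSE],
                            subplots, "guild")
  cca$guild_without <- cca_block("guild_without_reference", Yg0, env, cfg)
  if (ref %in% colnames(Ys)) {
    Ys0 <- Ys[, setdiff(colnames(Ys), ref), drop = FALSE]
    cca$species_without <- cca_block("species_without_reference", Ys0, env, cfg)
  } else {
    cca$species_without <- list(label = "species_without_reference",
                                error = "reference species not retained")
  }

  structure(
    list(units = units, intertype = intertype, cca = cca,
         guild_summary = summarize_guilds(stems, window, total_registered),
         retained_species = species,
         provenance = list(seed = cfg$seed, config = unclass(cfg),
                           n_stems = nrow(stems),
                           window_area_ha = window_area_ha(window),
                           package_version =
                             as.character(utils::packageVersion("stemspat")))),
    class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Study report: %d analysis units, %d intertype pairs\n",
              length(x$units), length(x$intertype)))
  for (u in x$units) {
    cls <- u$pattern$classification %||% "error"
    cat(sprintf("  %-8s %-7s n=%5d  pattern=%-10s extent=%s m  I1>env: %s\n",
                u$unit, u$kind, u$n, cls,
                format(u$pattern$extent_m %||% NA),
                format(u$moran$short_range_positive %||% NA)))
  }
  for (b in x$cca) {
    if (!is.null(b$error)) cat(sprintf("  CCA %s: %s\n", b$label, b$error))
    else cat(sprintf("  CCA %-26s constrained %.2f%%\n", b$label,
                     100 * b$proportion_constrained))
  }
  invisible(x)
}

#' Write a study report to disk
#'
#' `report.json` holds the machine-readable summary (classifications,
#' extents, Moran flags, Mantel and CCA tables, provenance); per-unit CSVs
#' hold the PCF envelope curves and correlograms.
#'
#' @param report a `study_report` from [run_study].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summ <- list(
    units = lapply(report$units, function(u) list(
      unit = u$unit, kind = u$kind, n = u$n, density_ha = u$density_ha,
      classification = u$pattern$classification %||% NA,
      extent_m = u$pattern$extent_m %||% NA,
      short_range_positive = u$moran$short_range_positive %||% NA,
      mantel_r = u$moran$mantel_r %||% NA,
      mantel_p = u$moran$mantel_p %||% NA,
      interpret_correlogram = u$moran$interpret %||% NA,
      error = u$pattern$error %||% u$moran$error %||% NULL)),
    intertype = lapply(report$intertype, function(it) list(
      pair = it$pair,
      short_range_positive = it$short_range_positive %||% NA,
      error = it$error %||% NULL)),
    cca = lapply(report$cca, function(b) if (!is.null(b$error))
      list(label = b$label, error = b$error)
      else list(label = b$label,
                proportion_constrained = b$proportion_constrained,
                selected_terms = b$selected_terms,
                margin = b$margin, model = b$model,
                decomposition = b$decomposition)),
    guild_summary = report$guild_summary,
    target_share_pct = attr(report$guild_summary, "target_share_pct"),
    retained_species = report$retained_species,
    provenance = report$provenance)
  jsonlite::write_json(summ, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", force = TRUE)
  for (nm in names(report$units)) {
    u <- report$units[[nm]]
    if (!is.null(u$pattern$envelope)) {
      e <- u$pattern$envelope
      utils::write.csv(data.frame(r = e$r, g_obs = e$g_obs, g_lo = e$g_lo,
                                  g_hi = e$g_hi),
                       file.path(dir, paste0(nm, "_pcf.csv")),
                       row.names = FALSE)
    }
    if (!is.null(u$moran$correlogram))
      utils::write.csv(u$moran$correlogram,
                       file.path(dir, paste0(nm, "_correlogram.csv")),
                       row.names = FALSE)
  }
  invisible(dir)
}
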