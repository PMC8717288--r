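# Stem-map data model and delimited-text io.

#' Regeneration guild codes
#'
#' SLP = short-lived pioneer, LLP = long-lived pioneer, NPLD = non-pioneer
#' light demander, STS = shade tolerant.
#' @export
GUILDS <- c("SLP", "LLP", "NPLD", "STS")

#' Minimum diameter at breast height retained by the survey (cm)
#' @export
DBH_MIN <- 10

#' Construct and validate a stem table
#'
#' A stem table is one row per tree: `tree_id`, `transect_id`, `x`, `y`
#' (metres in the window's global frame), `species`, `guild`, `dbh` (cm).
#' Validation enforces the survey threshold `dbh >= 10`, membership of every
#' stem in the declared window, and known guild codes.
#'
#' @param df data frame with at least `tree_id`, `transect_id`, `x`, `y`,
#'   `species`, `guild`, `dbh`.
#' @param window a [transect_window] the coordinates must lie in, or `NULL`
#'   to skip the geometric check.
#' @return the validated data frame with class `stem_table` and the window
#'   attached as attribute `window`.
#' @export
stem_table <- function(df, window = NULL) {
  need <- c("tree_id", "transect_id", "x", "y", "species", "guild", "dbh")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(df$x) || !is.numeric(df$y) || !is.numeric(df$dbh))
    stop("x, y and dbh must be numeric")
  if (nrow(df) && any(df$dbh < DBH_MIN))
    stop("dbh below the ", DBH_MIN, " cm survey threshold")
  bad <- setdiff(unique(df$guild), GUILDS)
  if (length(bad)) stop("unknown guild code(s): ", paste(bad, collapse = ", "))
  if (!is.null(window) && nrow(df)) {
    tid <- locate_transect(window, df$x, df$y)
    if (anyNA(tid))
      stop("stem(s) outside the declared window: ",
           paste(utils::head(df$tree_id[is.na(tid)], 5), collapse = ", "))
  }
  structure(as.data.frame(df), class = c("stem_table", "data.frame"),
            window = window)
}

#' @export
print.stem_table <- function(x, ...) {
  cat(sprintf("Stem table: %d stems, %d species, guilds: %s\n",
              nrow(x), length(unique(x$species)),
              paste(intersect(GUILDS, unique(x$guild)), collapse = ", ")))
  NextMethod()
}

#' Read a species-to-guild lookup table
#'
#' Comma-separated with header `species,guild` (an optional `deciduousness`
#' column is carried through).
#'
#' @param path file path.
#' @return data frame.
#' @export
read_species_lookup <- function(path) {
  lk <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("species", "guild"), names(lk))
  if (length(miss)) stop("lookup missing column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(lk$guild), GUILDS)
  if (length(bad)) stop("lookup has unknown guild code(s): ", paste(bad, collapse = ", "))
  lk
}

#' Read a stem map from delimited text
#'
#' Expects a comma-separated file with header columns `tree_id`, `transect_id`,
#' `x`, `y`, `species`, `dbh`. The regeneration guild is attached from the
#' species lookup. Rows with `dbh` below the 10 cm survey threshold are
#' rejected (their count is reported in attribute `n_rejected`); non-numeric
#' coordinates or diameters and unknown species codes are errors.
#'
#' @param path file path.
#' @param lookup species lookup: a data frame with `species` and `guild`
#'   columns (see [read_species_lookup]).
#' @param window optional [transect_window] used for validation.
#' @return a [stem_table] with attribute `n_rejected`.
#' @export
read_stem_map <- function(path, lookup, window = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("tree_id", "transect_id", "x", "y", "species", "dbh")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("stem map missing column(s): ", paste(miss, collapse = ", "))
  num <- function(col) suppressWarnings(as.numeric(raw[[col]]))
  x <- num("x"); y <- num("y"); dbh <- num("dbh")
  bad <- which(is.na(x) | is.na(y) | is.na(dbh))
  if (length(bad))
    stop("non-numeric coordinate or dbh at data line(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  unknown <- setdiff(unique(raw$species), lookup$species)
  if (length(unknown))
    stop("species code(s) absent from lookup: ", paste(unknown, collapse = ", "))
  keep <- dbh >= DBH_MIN
  df <- data.frame(
    tree_id = raw$tree_id[keep], transect_id = raw$transect_id[keep],
    x = x[keep], y = y[keep], species = raw$species[keep],
    guild = lookup$guild[match(raw$species[keep], lookup$species)],
    dbh = dbh[keep], stringsAsFactors = FALSE
  )
  st <- stem_table(df, window)
  attr(st, "n_rejected") <- sum(!keep)
  st
}

#' Write a stem table as CSV
#'
#' @param stems a [stem_table].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stem_map <- function(stems, path) {
  utils::write.csv(
    stems[, c("tree_id", "transect_id", "x", "y", "species", "dbh")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Keep only species with enough individuals
#'
#' Species-level analyses are restricted to species with at least `min_n`
#' stems; all stems of rarer species are removed.
#'
#' @param stems a [stem_table].
#' @param min_n minimum number of individuals per retained species.
#' @return the filtered [stem_table]; retained species codes in attribute
#'   `retained_species`.
#' @export
filter_species <- function(stems, min_n = 50) {
  stopifnot(min_n >= 1)
  tab <- table(stems$species)
  keep <- names(tab)[tab >= min_n]
  out <- stems[stems$species %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out <- structure(out, class = class(stems), window = attr(stems, "window"))
  attr(out, "retained_species") <- keep
  out
}

#' Standardize diameters to the species mean
#'
#' Adds a `dbh_std` column equal to `dbh` divided by the mean dbh of the
#' stem's species, so that each species' standardized marks average exactly 1.
#' Guild-level autocorrelation analyses use this mark to avoid blurring by
#' interspecific differences in growth rate and maximum size; species-level
#' analyses use the raw dbh.
#'
#' @param stems a [stem_table].
#' @return the stem table with a `dbh_std` column.
#' @export
standardize_dbh_by_species <- function(stems) {
  singletons <- names(which(table(stems$species) == 1))
  if (length(singletons))
    warning("species with a single stem get standardized mark 1: ",
            paste(singletons, collapse = ", "))
  mu <- tapply(stems$dbh, stems$species, mean)
  stems$dbh_std <- stems$dbh / as.numeric(mu[stems$species])
  stems
}

#' Stand density of a regeneration guild
#'
#' @param stems a [stem_table].
#' @param window a [transect_window].
#' @param guild one of `r paste(GUILDS, collapse = ", ")`.
#' @return trees per hectare.
#' @export
guild_density <- function(stems, window, guild) {
  stopifnot(guild %in% GUILDS)
  a <- window_area_ha(window)
  if (a <= 0) stop("window area must be positive")
  sum(stems$guild == guild) / a
}

#' Subplot-level abundance matrix
#'
#' Cross-tabulates stems by subplot and species (or guild). Every stem must be
#' assignable to exactly one subplot; subplots without any target stem are
#' retained as all-zero rows so the community matrix covers the whole grid.
#'
#' @param stems a [stem_table].
#' @param subplots subplot grid from [make_subplots].
#' @param by `"species"` or `"guild"`.
#' @return integer matrix, rows = subplots (rownames = `subplot_id`),
#'   columns = species or guild codes.
#' @export
tabulate_abundance <- function(stems, subplots, by = c("species", "guild")) {
  by <- match.arg(by)
  units <- if (by == "species") sort(unique(stems$species)) else
    intersect(GUILDS, unique(stems$guild))
  m <- matrix(0L, nrow(subplots), max(length(units), 1L),
              dimnames = list(subplots$subplot_id,
                              if (length(units)) units else "none"))
  if (!length(units)) return(m[, 0, drop = FALSE])
  if (nrow(stems)) {
    sp_id <- assign_subplot(stems, subplots)
    tab <- table(factor(sp_id, levels = subplots$subplot_id),
                 factor(stems[[by]], levels = units))
    m[] <- as.integer(tab)
  }
  m
}

#' Per-guild counts, densities and the target share
#'
#' @param stems a [stem_table].
#' @param window a [transect_window].
#' @param total_registered optional total number of trees registered in the
#'   survey (all species); when given, the share of the target stems among
#'   them is reported as a percentage.
#' @return data frame with one row per guild (`guild`, `n`, `density_ha`);
#'   attribute `target_share_pct` when `total_registered` is supplied.
#' @export
summarize_guilds <- function(stems, window, total_registered = NULL) {
  a <- window_area_ha(window)
  n <- vapply(GUILDS, function(g) sum(stems$guild == g), integer(1))
  out <- data.frame(guild = GUILDS, n = as.integer(n), density_ha = n / a,
                    stringsAsFactors = FALSE)
  if (!is.null(total_registered))
    attr(out, "target_share_pct") <- 100 * nrow(stems) / total_registered
  out
}

#' Read / write a subplot environment table
#'
#' Comma-separated with header `subplot_id, transect_id, cx, cy, slope_pct,
#' topography, altitude_m, dist_water_m`. Topography must be one of `flat`,
#' `slope`, `crest`, `shallow`; slopes must be non-negative.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_environment <- function(path) {
  env <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subplot_id", "transect_id", "cx", "cy", "slope_pct",
            "topography", "altitude_m", "dist_water_m")
  miss <- setdiff(need, names(env))
  if (length(miss)) stop("environment table missing column(s): ",
                         paste(miss, collapse = ", "))
  validate_environment(env)
  env
}

#' @rdname read_environment
#' @param env environment data frame.
#' @export
write_environment <- function(env, path) {
  validate_environment(env)
  utils::write.csv(env, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_environment <- function(env) {
  bad <- setdiff(unique(env$topography), c("flat", "slope", "crest", "shallow"))
  if (length(bad)) stop("unknown topography categor(ies): ", paste(bad, collapse = ", "))
  if (any(env$slope_pct < 0)) stop("negative slope")
  invisible(env)
}
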