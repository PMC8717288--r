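# Shared fixtures: tiny windows, lookup tables, and stem-map writers used
# across the test files. Everything is generated in code at test time.

fix_lookup <- function() {
  data.frame(
    species = c("MUSCE", "MACMO", "PERIE", "PETER", "GILBE"),
    guild = c("SLP", "SLP", "LLP", "NPLD", "STS"),
    deciduousness = c("deciduous", "deciduous", "deciduous", "semi", "evergreen"),
    stringsAsFactors = FALSE)
}

# one short transect, handy for io tests
fix_window <- function() transect_window(1000)

# desk-scale window used for scenario-recovery runs: 4 x 3000 m = 60 ha
desk_window <- function() transect_window(rep(3000, 4))

fix_stem_df <- function() {
  data.frame(
    tree_id = c("t1", "t2", "t3"),
    transect_id = "T1",
    x = c(10, 500, 990), y = c(5, 25, 45),
    species = c("MUSCE", "PERIE", "GILBE"),
    dbh = c(12.5, 40, 33.3),
    stringsAsFactors = FALSE)
}

write_stem_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# uniform random marked stems in a window (fixed seed)
random_stems <- function(n, window, seed, species = "MUSCE", guild = "SLP") {
  set.seed(seed)
  r <- window$rectangles
  k <- sample(nrow(r), n, replace = TRUE, prob = (r$xmax - r$xmin))
  data.frame(
    tree_id = sprintf("s%04d", seq_len(n)), transect_id = r$transect_id[k],
    x = runif(n, r$xmin[k], r$xmax[k]), y = runif(n, r$ymin[k], r$ymax[k]),
    species = species, guild = guild,
    dbh = rlnorm(n, log(30), 0.4) + 10, stringsAsFactors = FALSE)
}
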