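# Small fixtures built in code, shared across test files.

# A consistent set of the five input tables: 7 plots, two of which carry the
# two-species community used for hand-computed CWM checks.
make_toy_tables <- function() {
  meta <- data.frame(
    plot_id = paste0("p", 1:7),
    latitude = c(50.0, 50.1, 50.2, 50.3, 50.4, 50.5, 50.6),
    longitude = c(10.0, 10.1, 10.2, 10.3, 10.4, 10.5, 10.6),
    survey_year = c(2000, 2001, 2002, 2003, 2004, 2005, 2006),
    abundance_type = "cover",
    stringsAsFactors = FALSE
  )
  veg <- data.frame(
    plot_id = c("p1", "p1", "p2", "p3", "p3", "p4", "p5", "p6", "p7"),
    species = c("Alpha alta", "Beta brevis", "Alpha alta", "Gamma grandis",
                "Delta dubia", "Alpha alta", "Beta brevis", "Gamma grandis",
                "Alpha alta"),
    cover = c(60, 40, 70, 50, 50, 30, 20, 80, 90),
    stringsAsFactors = FALSE
  )
  traits <- data.frame(
    taxon = c("Alpha alta", "Beta brevis", "Gamma grandis", "Delta"),
    taxon_rank = c("species", "species", "species", "genus"),
    plant_height = c(10, 20, 5, 2),
    sla = c(15, 25, 30, 12),
    seed_mass = c(1, 2, 0.5, 3),
    srl = c(100, 120, 80, 90),
    stringsAsFactors = FALSE
  )
  habitat <- data.frame(
    plot_id = paste0("p", 1:7),
    level1 = c("A", "A", "B", "B", "A", "B", "A"),
    level2 = c("A1", "A1", "B1", "B2", "A2", "B1", "A1"),
    level3 = c("A1.1", "A1.2", "B1.1", "B2.1", "A2.1", "B1.2", "A1.1"),
    stringsAsFactors = FALSE
  )
  climate <- data.frame(plot_id = paste0("p", 1:7), stringsAsFactors = FALSE)
  set.seed(99)
  for (j in 1:19) climate[[paste0("bio", j)]] <- rnorm(7, mean = j)
  list(meta = validate_table(meta, "plot_metadata"),
       veg = validate_table(veg, "vegetation"),
       traits = validate_table(traits, "traits"),
       habitat = validate_table(habitat, "habitat"),
       climate = validate_table(climate, "climate"))
}

# Small synthetic dataset reused by several model tests.
small_dataset <- function(seed = 7, n = 1200, tau1 = c(0.2, 0, 0, 0),
                          tau0 = 0.5, ...) {
  cfg <- synthetic_config(n_plots = n, n_habitats_per_level = c(4, 8, 16),
                          tau0_sq = tau0, tau1_sq = tau1, seed = seed, ...)
  generate_dataset(cfg)
}
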