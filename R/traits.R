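#' Default morphometric trait set for threespine stickleback
#'
#' Returns the ten traits used throughout the package, in their documented
#' order: eight linear measurements (mm) taken with calipers and two meristic
#' counts (lateral plate number, gill raker number). For each trait the table
#' carries the default marine mean, the default freshwater offset (the
#' habitat contrast applied identically to every freshwater site), the
#' within-site standard deviations by habitat, and the default allometric
#' slope of the trait on standard length.
#'
#' Within-site SDs default to the square roots of published marine and
#' freshwater within-habitat variances for these traits (e.g., body depth
#' variance 0.26 in both habitats; lateral plate variance 0.02 in marine
#' fish, which are nearly uniformly fully plated, versus 1.02 in freshwater).
#' Means and offsets are realistic values for ~50 mm standard-length fish:
#' freshwater populations are deeper-bodied, with shorter spines, fewer
#' lateral plates and fewer gill rakers than marine fish.
#'
#' @return A data frame with columns `trait`, `type` (`"linear"` or
#'   `"count"`), `marine_mean`, `freshwater_offset`, `marine_sd`,
#'   `freshwater_sd`, `allometric_slope`.
#' @export
#' @examples
#' stickleback_traits()
stickleback_traits <- function() {
  data.frame(
    trait = c("body_depth", "pelvic_spine", "pelvic_girdle",
              "dorsal_spine_1", "dorsal_spine_2", "mouth_width",
              "eye_diameter", "caudal_peduncle", "lateral_plates",
              "gill_rakers"),
    type = c(rep("linear", 8L), "count", "count"),
    marine_mean = c(11.0, 8.5, 12.0, 5.0, 5.5, 4.5, 4.8, 2.5, 32, 21),
    freshwater_offset = c(1.0, -1.5, -1.5, -0.6, -0.7, -0.2, 0.2, -0.2,
                          -25, -2),
    marine_sd = sqrt(c(0.26, 0.26, 0.61, 0.61, 0.32, 0.11, 0.06, 0.02,
                       0.02, 10.64)),
    freshwater_sd = sqrt(c(0.26, 1.33, 1.76, 0.51, 0.55, 0.09, 0.08, 0.01,
                           1.02, 6.92)),
    allometric_slope = c(0.20, 0.15, 0.22, 0.09, 0.10, 0.08, 0.07, 0.05,
                         0, 0),
    stringsAsFactors = FALSE
  )
}

#' Trait column names of a specimen table
#'
#' Identifies which columns of a specimen table are trait measurements,
#' i.e., everything except the identifier columns `site`, `habitat` and
#' `standard_length`.
#'
#' @param table A specimen data frame.
#' @return Character vector of trait column names.
#' @export
trait_columns <- function(table) {
  setdiff(colnames(table), c("fish_id", "site", "habitat", "standard_length"))
}

# Default study layout: 10 marine + 6 freshwater sites with per-site sample
# sizes between 20 and 60 fish, and approximate coastal British Columbia
# coordinates (synthetic stand-ins for real sampling locations).
default_site_layout <- function() {
  data.frame(
    site = c("Kanaka Creek", "Courtenay River Estuary", "Canton Lagoon",
             "Sayward Estuary", "Sooke River", "Bowen Lagoon",
             "Belcarra Inlet", "Englishman River Estuary",
             "Port Hardy Estuary", "Bamfield Inlet",
             "Mohun Lake", "Muchalat Lake", "Comox Lake", "Lil Mud Lake",
             "Lower Campbell Lake", "Mccreight Lake"),
    habitat = c(rep("marine", 10L), rep("freshwater", 6L)),
    n = c(20L, 39L, 40L, 38L, 22L, 60L, 60L, 25L, 20L, 27L,
          29L, 25L, 30L, 30L, 30L, 29L),
    latitude = c(49.20, 49.68, 48.86, 50.38, 48.38, 49.38, 49.31, 49.31,
                 50.72, 48.83,
                 50.13, 49.87, 49.62, 50.27, 50.03, 50.37),
    longitude = c(-122.56, -124.98, -125.13, -125.96, -123.72, -123.33,
                  -122.92, -124.28, -127.49, -125.14,
                  -125.38, -126.33, -125.10, -125.53, -125.45, -125.70),
    stringsAsFactors = FALSE
  )
}
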