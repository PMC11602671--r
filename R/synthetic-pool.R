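# Synthetic species pools: traits, taxonomy and zone affinity.

#' Trait scheme used throughout the package
#'
#' Six categorical traits describing the ecological role of a reef fish:
#' maximum length (6 ordered size classes), mobility (4 ordered levels),
#' activity period (day/night), gregariousness (4 ordered levels), position
#' in the water column (3 ordered levels) and diet (6 nominal categories).
#'
#' @return named list; each element has `levels` (character) and `ordered`
#'   (logical).
#' @export
trait_scheme <- function() {
  list(
    max_length = list(
      levels = c("0-7", "7-15", "15-30", "30-50", "50-80", ">80"),
      ordered = TRUE
    ),
    mobility = list(
      levels = c("sedentary", "small_range", "wide_range", "highly_mobile"),
      ordered = TRUE
    ),
    activity = list(levels = c("day", "night"), ordered = FALSE),
    gregariousness = list(
      levels = c("solitary", "pairs", "small_schools", "large_schools"),
      ordered = TRUE
    ),
    position = list(
      levels = c("benthic", "benthopelagic", "pelagic"),
      ordered = TRUE
    ),
    diet = list(
      levels = c("herbivore_detritivore", "sessile_invertivore",
                 "mobile_invertivore", "planktivore", "piscivore", "omnivore"),
      ordered = FALSE
    )
  )
}

.taxonomy_levels <- c("genus", "family", "order", "subclass", "class", "superclass")

#' Configuration for a synthetic species pool
#'
#' @param n_species number of species in the regional pool.
#' @param prop_shared,prop_shallow_only,prop_deep_only fractions of the pool
#'   shared between strata, exclusive to the shallow zone, and exclusive to
#'   the mesophotic zone. Must sum to 1; pool sizes are obtained by
#'   largest-remainder rounding, so the defaults reproduce (52, 29, 15) for
#'   96 species.
#' @param trait_category_sets trait scheme as returned by [trait_scheme()];
#'   each trait needs at least two categories.
#' @param taxonomy_shape named integer vector giving the number of distinct
#'   genera, families, orders, subclasses, classes and superclasses; counts
#'   must be non-increasing up the hierarchy.
#' @param seed integer seed; all pool randomness derives from it.
#' @return a `pool_config` list.
#' @export
pool_config <- function(n_species = 96,
                        prop_shared = 0.54,
                        prop_shallow_only = 0.30,
                        prop_deep_only = 0.16,
                        trait_category_sets = trait_scheme(),
                        taxonomy_shape = c(genus = 65, family = 35, order = 18,
                                           subclass = 4, class = 2, superclass = 1),
                        seed = 1L) {
  props <- c(shared = prop_shared, shallow_only = prop_shallow_only,
             deep_only = prop_deep_only)
  if (any(props < 0) || any(props > 1) || abs(sum(props) - 1) > 1e-9) {
    stop_config("zone-affinity proportions must lie in [0,1] and sum to 1")
  }
  if (n_species < 1) stop_config("n_species must be >= 1")
  nlev <- vapply(trait_category_sets, function(t) length(t$levels), integer(1))
  if (any(nlev < 2)) stop_config("every trait needs at least two categories")
  shape <- taxonomy_shape[.taxonomy_levels]
  if (any(is.na(shape))) stop_config("taxonomy_shape must name all six levels")
  if (any(diff(as.numeric(shape)) > 0)) {
    stop_config("taxonomy counts must be non-increasing up the hierarchy")
  }
  if (shape[["genus"]] > n_species) stop_config("more genera than species")
  structure(
    list(n_species = as.integer(n_species), props = props,
         traits = trait_category_sets, taxonomy_shape = shape,
         seed = as.integer(seed)),
    class = "pool_config"
  )
}

# Surjective assignment of n children onto k parent labels: every parent gets
# at least one child, remainder assigned uniformly.
.surjection <- function(n, k, labels) {
  stopifnot(k <= n)
  idx <- c(seq_len(k), sample.int(k, n - k, replace = TRUE))
  labels[sample(idx)]
}

#' Generate a synthetic species pool
#'
#' Draws a pool of species with (i) one category per trait, sampled uniformly
#' and independently; (ii) a full six-level Linnaean lineage with consistent
#' nesting (each genus maps to one family, each family to one order, ...);
#' and (iii) a zone-affinity label partitioning the pool into species shared
#' between strata, exclusive to the shallow zone, and exclusive to the
#' mesophotic zone, with sizes fixed by largest-remainder rounding of the
#' configured fractions.
#'
#' @param cfg a [pool_config()].
#' @return list with elements `traits` (data.frame, species x 6 traits),
#'   `taxonomy` (data.frame, species x 6 ranks), `affinity` (data.frame with
#'   `species`, `affinity`), and `partition` (named integer counts).
#' @export
generate_species_pool <- function(cfg = pool_config()) {
  stopifnot(inherits(cfg, "pool_config"))
  with_seed(derive_seed(cfg$seed, "pool"), {
    n <- cfg$n_species
    species <- sprintf("sp%03d", seq_len(n))

    traits <- data.frame(species = species, stringsAsFactors = FALSE)
    for (tr in names(cfg$traits)) {
      traits[[tr]] <- sample(cfg$traits[[tr]]$levels, n, replace = TRUE)
    }

    # consistent nested lineage: species -> genus -> family -> ... -> superclass
    shape <- cfg$taxonomy_shape
    taxonomy <- data.frame(species = species, stringsAsFactors = FALSE)
    parent <- species
    for (lv in .taxonomy_levels) {
      k <- shape[[lv]]
      units <- unique(parent)
      lab <- paste0(substr(lv, 1, 3), sprintf("%03d", seq_len(k)))
      if (k > length(units)) k <- length(units) # cannot exceed children
      map <- stats::setNames(.surjection(length(units), k, lab[seq_len(k)]), units)
      taxonomy[[lv]] <- unname(map[parent])
      parent <- taxonomy[[lv]]
    }

    sizes <- largest_remainder(n, cfg$props)
    affinity <- data.frame(
      species = species,
      affinity = rep(c("shared", "shallow_only", "deep_only"), times = sizes),
      stringsAsFactors = FALSE
    )
    list(traits = traits, taxonomy = taxonomy, affinity = affinity,
         partition = stats::setNames(sizes, names(cfg$props)))
  })
}
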