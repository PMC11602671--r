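# Survey ingestion, filtering, community matrix, PIT summaries, Venn partition.

.required_cols <- c("transect_id", "site", "depth", "season", "year",
                    "species", "count", "quality_flag")
.valid_flags <- c("ok", "dragged", "parallel_swim")

#' Read and validate survey records
#'
#' Accepts a CSV path or an in-memory data.frame. Checks the schema (all
#' required columns present), coerces types, and validates counts (integer,
#' non-negative) and quality flags (closed set: `ok`, `dragged`,
#' `parallel_swim`).
#'
#' @param x CSV file path or data.frame of raw records.
#' @return validated data.frame of survey records.
#' @export
read_survey_records <- function(x) {
  rec <- if (is.character(x)) utils::read.csv(x, stringsAsFactors = FALSE) else x
  stopifnot(is.data.frame(rec))
  miss <- setdiff(.required_cols, names(rec))
  if (length(miss)) {
    stop("survey records are missing column(s): ", paste(miss, collapse = ", "))
  }
  rec$count <- suppressWarnings(as.numeric(rec$count))
  bad <- which(!is.finite(rec$count) | rec$count < 0 | rec$count != round(rec$count))
  if (length(bad)) {
    stop("invalid count at row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  rec$count <- as.integer(rec$count)
  badf <- which(!rec$quality_flag %in% .valid_flags)
  if (length(badf)) {
    stop("unknown quality flag at row(s): ", paste(utils::head(badf, 5), collapse = ", "))
  }
  if (any(!is.finite(rec$depth) | rec$depth < 0)) stop("depths must be >= 0")
  rec
}

#' Drop records compromised by ROV drag or parallel-swimming fish
#'
#' Removes rows whose quality flag marks the record as unusable (the ROV was
#' dragged by currents, or the fish swam parallel to the vehicle and may be a
#' re-count). The number of removed rows is reported via `message()`.
#'
#' @param records validated records from [read_survey_records()].
#' @return filtered data.frame.
#' @export
filter_records <- function(records) {
  drop <- records$quality_flag != "ok"
  if (all(drop)) warning("all records were flagged; empty survey returned")
  message(sum(drop), " flagged record(s) removed, ", sum(!drop), " retained")
  records[!drop, , drop = FALSE]
}

#' Build the transect x species community matrix
#'
#' Aggregates filtered records into one row per transect with species counts
#' as columns, attaches the depth stratum via [assign_stratum()], and adds
#' per-transect species richness `S` and total abundance `N`. Duplicate
#' (transect, species) rows are summed with a warning. Species never observed
#' are not given columns.
#'
#' @param records filtered survey records.
#' @param upper_limit stratum boundary depth (m) passed to [assign_stratum()].
#' @return a `community_matrix`: data.frame with metadata columns
#'   (`transect_id`, `site`, `stratum`, `season`, `year`, `depth`, `S`, `N`)
#'   followed by integer species columns; species names in
#'   `attr(, "species")`.
#' @export
build_community_matrix <- function(records, upper_limit = 21) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  key <- paste(records$transect_id, records$species, sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate (transect, species) rows summed")
    agg <- stats::aggregate(count ~ transect_id + species, records, sum)
    meta <- records[!duplicated(records$transect_id),
                    c("transect_id", "site", "season", "year", "depth")]
    records <- merge(agg, meta, by = "transect_id")
  }
  tid <- sort(unique(records$transect_id))
  spp <- sort(unique(records$species[records$count > 0]))
  m <- matrix(0L, nrow = length(tid), ncol = length(spp),
              dimnames = list(tid, spp))
  keep <- records$species %in% spp
  m[cbind(match(records$transect_id[keep], tid),
          match(records$species[keep], spp))] <- records$count[keep]

  meta <- records[!duplicated(records$transect_id),
                  c("transect_id", "site", "season", "year", "depth")]
  meta <- meta[match(tid, meta$transect_id), ]
  meta$stratum <- assign_stratum(meta$depth, upper_limit)
  out <- data.frame(meta[c("transect_id", "site", "stratum", "season", "year", "depth")],
                    S = as.integer(rowSums(m > 0)), N = as.integer(rowSums(m)),
                    m, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "species") <- spp
  class(out) <- c("community_matrix", "data.frame")
  out
}

#' Extract the count sub-matrix of a community matrix
#' @param cm a `community_matrix`.
#' @return integer matrix (transects x species) with transect_id rownames.
#' @export
community_counts <- function(cm) {
  spp <- attr(cm, "species")
  m <- as.matrix(cm[, spp, drop = FALSE])
  rownames(m) <- cm$transect_id
  storage.mode(m) <- "integer"
  m
}

#' Per-transect substrate composition from PIT records
#'
#' Converts point-intercept records into percentage cover of the four
#' substrate categories (sand, gravel, block, rock) per transect, carrying
#' through the per-transect coral metrics. Percentages are computed over the
#' points actually present; a warning is emitted for transects that deviate
#' from the 30-point protocol.
#'
#' @param pit data.frame from [generate_benthic_pit()] (or equivalent field
#'   records with `transect_id`, `substrate` and coral columns).
#' @param expected_points points per transect in the protocol (30).
#' @return data.frame, one row per transect: `sand`, `gravel`, `block`,
#'   `rock` percentages (summing to 100), `soft_coral`, `black_coral`,
#'   `hard_coral_pct`.
#' @export
pit_substrate_composition <- function(pit, expected_points = 30L) {
  cats <- c("sand", "gravel", "block", "rock")
  bad <- setdiff(unique(pit$substrate), cats)
  if (length(bad)) stop("unknown substrate label(s): ", paste(bad, collapse = ", "))
  tab <- table(factor(pit$transect_id, levels = unique(pit$transect_id)),
               factor(pit$substrate, levels = cats))
  npts <- rowSums(tab)
  if (any(npts != expected_points)) {
    warning(sum(npts != expected_points),
            " transect(s) deviate from the ", expected_points, "-point protocol")
  }
  pct <- sweep(unclass(tab), 1, npts, `/`) * 100
  out <- data.frame(transect_id = rownames(pct), pct,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (cc in intersect(c("soft_coral", "black_coral", "hard_coral_pct"), names(pit))) {
    out[[cc]] <- pit[[cc]][match(out$transect_id, pit$transect_id)]
  }
  rownames(out) <- NULL
  out
}

#' Venn partition of species by depth stratum
#'
#' Classifies each observed species as shared between strata, exclusive to
#' the shallow zone, or exclusive to the mesophotic zone, and returns the
#' counts together with the per-stratum and overall totals.
#'
#' @param cm a `community_matrix` containing both strata.
#' @return a `venn_partition` list: `shared`, `shallow_only`, `deep_only`,
#'   `shallow_total`, `deep_total`, `overall`, `shared_fraction`, and the
#'   species name vectors in `species`.
#' @export
venn_partition <- function(cm) {
  stopifnot(inherits(cm, "community_matrix"))
  if (length(unique(cm$stratum)) < 2) {
    stop("venn_partition needs transects from both strata")
  }
  m <- community_counts(cm)
  in_sh <- colSums(m[cm$stratum == "shallow", , drop = FALSE]) > 0
  in_dp <- colSums(m[cm$stratum == "mesophotic", , drop = FALSE]) > 0
  sp <- colnames(m)
  out <- list(
    shared = sum(in_sh & in_dp),
    shallow_only = sum(in_sh & !in_dp),
    deep_only = sum(!in_sh & in_dp),
    shallow_total = sum(in_sh),
    deep_total = sum(in_dp),
    overall = sum(in_sh | in_dp),
    shared_fraction = sum(in_sh & in_dp) / sum(in_sh | in_dp),
    species = list(shared = sp[in_sh & in_dp],
                   shallow_only = sp[in_sh & !in_dp],
                   deep_only = sp[!in_sh & in_dp])
  )
  class(out) <- "venn_partition"
  out
}

#' @exportS3Method base::print
print.venn_partition <- function(x, ...) {
  cat("Species Venn partition by stratum\n")
  cat(sprintf("  shared: %d (%.0f%%)  shallow-only: %d  mesophotic-only: %d\n",
              x$shared, 100 * x$shared_fraction, x$shallow_only, x$deep_only))
  cat(sprintf("  totals: shallow %d, mesophotic %d, overall %d\n",
              x$shallow_total, x$deep_total, x$overall))
  invisible(x)
}

#' Keep only transects rich enough for functional indices
#'
#' Convex-hull functional indices need at least as many species as trait
#' dimensions; transects with fewer than `min_richness` species are dropped.
#'
#' @param cm a `community_matrix`.
#' @param min_richness minimum species richness (default 6, the number of
#'   traits).
#' @return the filtered `community_matrix` (attributes preserved).
#' @export
functional_filter <- function(cm, min_richness = 6) {
  keep <- cm$S >= min_richness
  message(sum(keep), " transect(s) retained with S >= ", min_richness,
          "; ", sum(!keep), " dropped")
  out <- cm[keep, , drop = FALSE]
  attr(out, "species") <- attr(cm, "species")
  class(out) <- class(cm)
  out
}
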