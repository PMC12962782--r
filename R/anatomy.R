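# Tracing quantification arithmetic: input-cell fraction normalization for
# retrograde (monotranssynaptic) labeling, and axon density estimation from
# pixel-probability maps.

#' Per-region input-cell fractions, averaged across animals
#'
#' For each animal, the labeled-cell count of every input region is expressed
#' as a percentage of that animal's total labeled cells (controlling for
#' viral spread/efficiency); the percentages are then averaged across animals
#' with their SEM. Regions absent in an animal count as 0%; animals with zero
#' total labeled cells are excluded with a warning.
#'
#' @param counts data.frame with columns \code{animal_id, region, count}
#'   (nonnegative integers).
#' @return data.frame \code{region, mean_pct, sem_pct, n_animals}, sorted by
#'   decreasing mean; the per-animal percentage matrix (animals x regions) is
#'   attached as attribute \code{"per_animal"}.
#' @export
inputFractions <- function(counts) {
    stopifnot(all(c("animal_id", "region", "count") %in% names(counts)))
    if (any(counts$count < 0)) stop("counts must be nonnegative")
    totals <- tapply(counts$count, counts$animal_id, sum)
    zero <- names(totals)[totals == 0]
    if (length(zero)) {
        warning("animal(s) with zero labeled cells excluded: ",
                paste(zero, collapse = ", "))
        counts <- counts[!counts$animal_id %in% zero, , drop = FALSE]
    }
    if (!nrow(counts)) stop("no animal with labeled cells")
    animals <- sort(unique(counts$animal_id))
    regions <- sort(unique(counts$region))
    pct <- matrix(0, length(animals), length(regions),
                  dimnames = list(animals, regions))
    for (i in seq_len(nrow(counts)))
        pct[as.character(counts$animal_id[i]),
            as.character(counts$region[i])] <-
            pct[as.character(counts$animal_id[i]),
                as.character(counts$region[i])] + counts$count[i]
    pct <- pct / rowSums(pct) * 100
    out <- data.frame(region = regions,
                      mean_pct = colMeans(pct),
                      sem_pct = apply(pct, 2L, function(v)
                          if (length(v) > 1L) sem(v) else 0),
                      n_animals = nrow(pct),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$mean_pct), ]
    rownames(out) <- NULL
    attr(out, "per_animal") <- pct
    out
}

#' Axon density of a pixel-probability map
#'
#' Reduces a per-pixel axon-probability map (machine-learning segmentation
#' output, values in [0, 1]) to a scalar density, reported as a percentage:
#' either the mean pixel probability or the fraction of pixels at or above a
#' threshold.
#'
#' @param map numeric matrix of per-pixel axon probabilities in [0, 1].
#' @param mode "mean_probability" or "thresholded_fraction".
#' @param threshold probability threshold for the thresholded mode.
#' @return Density as a percentage in [0, 100].
#' @export
axonDensity <- function(map, mode = c("mean_probability",
                                      "thresholded_fraction"),
                        threshold = 0.5) {
    mode <- match.arg(mode)
    map <- as.matrix(map)
    if (!length(map)) stop("empty probability map")
    if (any(!is.finite(map)) || any(map < 0) || any(map > 1))
        stop("probabilities must be finite and within [0, 1]")
    100 * switch(mode,
                 mean_probability = mean(map),
                 thresholded_fraction = mean(map >= threshold))
}

#' Relative axon densities across sampled regions
#'
#' Per-region densities (see \code{\link{axonDensity}}) renormalized to
#' percentages across the sampled regions, as used for projection-density
#' summaries.
#'
#' @param maps named list of probability-map matrices, one per region.
#' @param mode,threshold passed to \code{\link{axonDensity}}.
#' @return data.frame \code{region, density_pct, share_pct} where
#'   \code{share_pct} sums to 100 across regions.
#' @export
axonDensityTable <- function(maps, mode = "mean_probability",
                             threshold = 0.5) {
    stopifnot(is.list(maps), length(maps) >= 1L, !is.null(names(maps)))
    dens <- vapply(maps, axonDensity, numeric(1L),
                   mode = mode, threshold = threshold)
    data.frame(region = names(maps), density_pct = unname(dens),
               share_pct = unname(dens / sum(dens) * 100),
               stringsAsFactors = FALSE)
}
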