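#' Normalized PAR-CLIP cross-linking density
#'
#' PAR-CLIP cross-link sites read out as T-to-C transitions. The density of
#' a region is its transition count divided by the number of T bases it
#' contains, scaled per million total transitions in the sample, making
#' densities comparable across regions of different T content and across
#' libraries of different depth. Regions with no T bases get NA (flagged).
#'
#' @param regions data.frame with columns \code{region}, \code{t_count}
#'   (number of T bases) and \code{transitions} (T-to-C event count);
#'   optionally a \code{class} column (CDS/5UTR/3UTR/intron,
#'   sense/antisense) carried through.
#' @return data.frame: region (+ class if given), t_count, transitions,
#'   density, no_t flag.
#' @export
parclip_density <- function(regions) {
  need <- c("region", "t_count", "transitions")
  if (!all(need %in% names(regions)))
    stop("regions must have columns ", paste(need, collapse = ", "))
  if (any(regions$transitions < 0) || any(regions$t_count < 0))
    stop("counts must be non-negative")
  total <- sum(regions$transitions)
  if (total <= 0) stop("no transitions in sample")
  no_t <- regions$t_count == 0
  density <- ifelse(no_t, NA_real_,
                    (regions$transitions / regions$t_count) * 1e6 / total)
  out <- regions[, intersect(c("region", "class", "t_count", "transitions"),
                             names(regions)), drop = FALSE]
  out$density <- density
  out$no_t <- no_t
  out
}

#' Relative cross-linking of two factors
#'
#' Regresses log2 density of one factor (e.g. Not4) on log2 density of a
#' reference factor (e.g. RNAPII) over regions where both are positive, and
#' classifies each region by its residual: more than
#' \code{log2(fold_cutoff)} above the fitted line is \code{"higher"} (more
#' cross-linking than expected from the global trend), below is
#' \code{"lower"}, else \code{"expected"}.
#'
#' @param density_a data.frame from \code{\link{parclip_density}} for the
#'   factor of interest.
#' @param density_ref Same, for the reference factor; joined on region.
#' @param fold_cutoff Fold deviation from the trend calling a region
#'   higher/lower (default 2, i.e. residual threshold of 1 log2 unit).
#' @return data.frame: region, log2_a, log2_ref, fitted, residual, class;
#'   attribute \code{fit} holds the lm coefficients.
#' @export
relative_crosslink <- function(density_a, density_ref, fold_cutoff = 2) {
  m <- merge(density_a[, c("region", "density")],
             density_ref[, c("region", "density")],
             by = "region", suffixes = c("_a", "_ref"))
  m <- m[!is.na(m$density_a) & !is.na(m$density_ref) &
           m$density_a > 0 & m$density_ref > 0, ]
  if (nrow(m) < 3) stop("too few regions with positive densities")
  la <- log2(m$density_a); lr <- log2(m$density_ref)
  fit <- stats::lm(la ~ lr)
  resid <- unname(stats::residuals(fit))
  thr <- log2(fold_cutoff)
  cls <- rep("expected", nrow(m))
  cls[resid > thr] <- "higher"
  cls[resid < -thr] <- "lower"
  out <- data.frame(region = m$region, log2_a = la, log2_ref = lr,
                    fitted = unname(stats::fitted(fit)), residual = resid,
                    class = cls, stringsAsFactors = FALSE)
  attr(out, "fit") <- stats::coef(fit)
  out
}
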