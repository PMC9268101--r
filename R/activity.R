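#' Activity unit conversions and class binning
#'
#' Potency is handled throughout the package as the half-maximal inhibitory
#' concentration IC50 in micromolar and its negative base-10 logarithm pIC50
#' (log units). Compounds are binned into the four activity classes used for
#' the antagonist series: most active (`++++`, IC50 <= 2 uM), active (`+++`,
#' 2-10 uM], moderately active (`++`, 10-20 uM] and inactive (`+`, > 20 uM).
#'
#' @param ic50 IC50 in micromolar; must be positive.
#' @return `pic50_from_ic50`: pIC50 in log units.
#' @examples
#' pic50_from_ic50(1)      # 0
#' classify_activity(0.43) # "++++"
#' @export
pic50_from_ic50 <- function(ic50) {
  if (any(!is.finite(ic50)) || any(ic50 <= 0))
    stop("IC50 must be positive and finite (given in micromolar)")
  -log10(ic50)
}

#' @rdname pic50_from_ic50
#' @param pic50 pIC50 in log units (micromolar scale).
#' @return `ic50_from_pic50`: IC50 in micromolar.
#' @export
ic50_from_pic50 <- function(pic50) {
  10^(-pic50)
}

#' @rdname pic50_from_ic50
#' @return `classify_activity`: character vector of class labels.
#' @export
classify_activity <- function(ic50) {
  if (any(!is.finite(ic50)) || any(ic50 <= 0))
    stop("IC50 must be positive and finite (given in micromolar)")
  cut(ic50, breaks = c(0, 2, 10, 20, Inf),
      labels = c("++++", "+++", "++", "+"),
      right = TRUE) |> as.character()
}

#' Signed error factor between measured and estimated IC50
#'
#' The ratio of the two activities with the larger value in the numerator, so
#' the magnitude is always >= 1. The sign reports the direction: positive
#' when the estimated IC50 is higher than (or equal to) the experimental
#' value, negative when it is lower.
#'
#' @param experimental measured IC50 (uM), positive.
#' @param estimated predicted IC50 (uM), positive.
#' @return signed ratio (vectorized).
#' @examples
#' error_factor(0.7, 1.7)  # +2.43
#' error_factor(684, 180)  # -3.8
#' @export
error_factor <- function(experimental, estimated) {
  if (any(experimental <= 0) || any(estimated <= 0))
    stop("error_factor needs positive IC50 values")
  mag <- pmax(experimental, estimated) / pmin(experimental, estimated)
  sgn <- ifelse(estimated >= experimental, 1, -1)
  sgn * mag
}

#' Pharmacophore hypothesis cost summary
#'
#' HypoGen-style hypotheses are scored in bits: the fixed cost of an ideal
#' model, the null cost of a model predicting every activity as the mean, and
#' the total cost of the actual hypothesis. The difference (null - total)
#' measures how much better than chance the hypothesis is; a difference above
#' 60 bits indicates a high (>90%) probability of true correlation, 40-60
#' bits a 70-90% predictability range, and below 40 bits low reliability.
#'
#' @param fixed fixed cost (bits), >= 0.
#' @param null null cost (bits), >= 0.
#' @param total total cost of the hypothesis (bits), >= 0.
#' @return object of class `cost_summary` with fields `fixed`, `null`,
#'   `total`, `difference` and `band`.
#' @examples
#' cost_summary(105.134, 215.593, 123.676)
#' @export
cost_summary <- function(fixed, null, total) {
  stopifnot(length(fixed) == 1L, length(null) == 1L, length(total) == 1L)
  if (any(c(fixed, null, total) < 0)) stop("costs must be non-negative (bits)")
  diff <- null - total
  band <- if (diff > 60) "high (>90%)" else if (diff >= 40) "70-90%" else "low"
  structure(list(fixed = fixed, null = null, total = total,
                 difference = diff, band = band),
            class = "cost_summary")
}

#' @export
print.cost_summary <- function(x, ...) {
  cat(sprintf(paste0("Pharmacophore cost summary (bits)\n",
                     "  fixed: %.3f  null: %.3f  total: %.3f\n",
                     "  cost difference (null - total): %.3f  [%s reliability]\n"),
              x$fixed, x$null, x$total, x$difference, x$band))
  invisible(x)
}

#' Join activity records onto molecular graphs
#'
#' Reads (or accepts) an activity table with columns `id` and `IC50_uM`,
#' validates it, and joins it onto a list of molecules by compound id. pIC50
#' and the four-level activity class are computed on the way in.
#'
#' @param graphs list of `molgraph` objects.
#' @param activities data.frame with columns `id`, `IC50_uM`, or a path to a
#'   CSV file with that header.
#' @return data.frame with one row per matched molecule: `id`, `IC50_uM`,
#'   `pIC50`, `class`, plus a `graph` list-column. Unmatched molecule ids are
#'   reported via a warning and dropped.
#' @export
attach_activities <- function(graphs, activities) {
  if (is.character(activities) && length(activities) == 1L)
    activities <- utils::read.csv(activities, stringsAsFactors = FALSE)
  if (!all(c("id", "IC50_uM") %in% names(activities)))
    stop("activity table must have columns 'id' and 'IC50_uM'")
  if (anyDuplicated(activities$id))
    stop("duplicate compound id(s) in activity table: ",
         paste(unique(activities$id[duplicated(activities$id)]), collapse = ", "))
  if (any(!is.finite(activities$IC50_uM) | activities$IC50_uM <= 0))
    stop("IC50_uM values must be positive; offending id(s): ",
         paste(activities$id[!is.finite(activities$IC50_uM) |
                               activities$IC50_uM <= 0], collapse = ", "))
  mol_ids <- vapply(graphs, function(g) g$id, "")
  hit <- match(mol_ids, activities$id)
  if (anyNA(hit))
    warning("no activity record for molecule(s): ",
            paste(mol_ids[is.na(hit)], collapse = ", "))
  keep <- which(!is.na(hit))
  ic50 <- activities$IC50_uM[hit[keep]]
  out <- data.frame(id = mol_ids[keep], IC50_uM = ic50,
                    pIC50 = pic50_from_ic50(ic50),
                    class = classify_activity(ic50),
                    stringsAsFactors = FALSE)
  out$graph <- graphs[keep]
  out
}
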