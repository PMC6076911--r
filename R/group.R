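#' Ranking table utilities
#'
#' A ranking table is a long-format data.frame with columns `subject`,
#' `group`, `band`, `roi`, `p` (trust probability) and `response_time`
#' (ms).  For every `(subject, band)` the `p` values sum to one over ROIs.
#'
#' @param table a ranking table
#' @param group group label to average
#' @return `mean_rankings`: a bands-by-ROIs matrix of arithmetic means over
#'   subjects
#' @export
mean_rankings <- function(table, group) {
  sub <- table[table$group == group, , drop = FALSE]
  if (nrow(sub) == 0)
    stop("mean_rankings: group '", group, "' not present", call. = FALSE)
  bands <- unique(table$band)
  rois <- unique(table$roi)
  m <- matrix(NA_real_, length(bands), length(rois),
              dimnames = list(bands, rois))
  agg <- stats::aggregate(p ~ band + roi, data = sub, FUN = mean)
  m[cbind(match(agg$band, bands), match(agg$roi, rois))] <- agg$p
  m
}

#' Compare group mean rankings
#'
#' Computes both groups' band-by-ROI mean trust probabilities, the
#' absolute difference surface, the per-band variance of the absolute
#' differences over ROIs, and their average over bands (the response-time
#' selection statistic).
#'
#' @param table a ranking table containing both groups
#' @param groups the two group labels (patient first)
#' @param var_fun variance convention over ROIs: `"population"` (divide by
#'   N, default) or `"sample"` (divide by N-1)
#' @return object of class `group_comparison`: list with `mean_p` (list of
#'   two matrices), `abs_diff`, `band_var`, `avg_var`, `diff` (signed
#'   patient - control), `response_time`
#' @export
group_comparison <- function(table, groups = c("patient", "control"),
                             var_fun = c("population", "sample")) {
  var_fun <- match.arg(var_fun)
  m1 <- mean_rankings(table, groups[1])
  m2 <- mean_rankings(table, groups[2])
  d <- m1 - m2
  ad <- abs(d)
  vfun <- function(x) {
    if (var_fun == "population") mean((x - mean(x))^2) else stats::var(x)
  }
  band_var <- apply(ad, 1, vfun)
  structure(list(mean_p = stats::setNames(list(m1, m2), groups),
                 diff = d, abs_diff = ad, band_var = band_var,
                 avg_var = mean(band_var),
                 response_time = unique(table$response_time)),
            class = "group_comparison")
}

#' Score response-time settings by group separation
#'
#' For each candidate response time, the variance (over ROIs) of the
#' absolute difference between the two groups' mean rankings is computed
#' per frequency band and averaged over bands; the response time with the
#' maximal average variance separates the groups best and is reported as
#' the selected setting.
#'
#' @param tables named list of ranking tables, one per response time
#'   (names = response time in ms), each containing both groups and the
#'   full band set
#' @param ... passed to [group_comparison()]
#' @return list with `scores` (data.frame `response_time`, `avg_var`),
#'   `selected` (response time with maximal score), `comparisons`
#' @export
response_time_score <- function(tables, ...) {
  comps <- lapply(tables, group_comparison, ...)
  scores <- data.frame(
    response_time = names(tables),
    avg_var = vapply(comps, function(cc) cc$avg_var, numeric(1)),
    row.names = NULL)
  list(scores = scores,
       selected = scores$response_time[which.max(scores$avg_var)],
       comparisons = comps)
}

#' Flag differentially ranked regions
#'
#' A region is flagged "increased" when the patient group's mean ranking
#' exceeds the control group's in at least `min_bands` frequency bands
#' (and "decreased" for the reverse).  `min_bands` equal to the number of
#' bands demands consistency across all bands; one less reproduces an
#' "all except one band" pattern.
#'
#' @param comp a [group_comparison()]
#' @param min_bands minimum number of agreeing bands (default: all bands)
#' @param direction flag increases, decreases, or both
#' @return data.frame with columns `roi`, `direction`, `n_bands`, `bands`
#'   (comma-joined band names); zero rows when nothing is flagged
#' @export
flag_abnormal_regions <- function(comp, min_bands = nrow(comp$diff),
                                  direction = c("increased", "both",
                                                "decreased")) {
  direction <- match.arg(direction)
  out <- list()
  scan <- function(mask, label) {
    hits <- colSums(mask)
    for (r in which(hits >= min_bands)) {
      out[[length(out) + 1L]] <<- data.frame(
        roi = colnames(mask)[r], direction = label,
        n_bands = hits[r],
        bands = paste(rownames(mask)[mask[, r]], collapse = ","))
    }
  }
  if (direction %in% c("increased", "both")) scan(comp$diff > 0, "increased")
  if (direction %in% c("decreased", "both")) scan(comp$diff < 0, "decreased")
  if (length(out) == 0)
    return(data.frame(roi = character(), direction = character(),
                      n_bands = integer(), bands = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Homologous-pair asymmetry of group mean rankings
#'
#' Derived left/right asymmetry column: difference of mean rankings
#' between homologous ROI pairs (by column index), per band and group.
#'
#' @param comp a [group_comparison()]
#' @param pairs 2-column matrix of ROI column indices (right, left);
#'   default the bilateral temporal (1, 2) and cuneus/precuneus (3, 4)
#'   pairs
#' @return data.frame `group`, `band`, `pair`, `asymmetry` (right minus
#'   left)
#' @export
ranking_asymmetry <- function(comp, pairs = rbind(c(1, 2), c(3, 4))) {
  n_roi <- ncol(comp$diff)
  pairs <- pairs[apply(pairs, 1, max) <= n_roi, , drop = FALSE]
  if (nrow(pairs) == 0)
    return(data.frame(group = character(), band = character(),
                      pair = character(), asymmetry = numeric()))
  res <- list()
  for (g in names(comp$mean_p)) {
    m <- comp$mean_p[[g]]
    for (k in seq_len(nrow(pairs))) {
      res[[length(res) + 1L]] <- data.frame(
        group = g, band = rownames(m),
        pair = paste(colnames(m)[pairs[k, ]], collapse = " vs "),
        asymmetry = m[, pairs[k, 1]] - m[, pairs[k, 2]])
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
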