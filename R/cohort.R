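# Cohort analysis: per-cell median summaries, percent median change from
# control to treatment, responder categorization, pooled frequency
# distributions, FLIRR vs E% correlation, and glycolysis attribution from the
# whole-cell vs mitochondrial comparison.

#' Per-cell summaries of ROI redox records
#'
#' Groups valid ROI records by (fov, cell, condition, morphology) and reports
#' the median — the cell-level statistic used throughout — plus the mean for
#' comparison. Cells with fewer than `min_rois` valid ROIs are excluded and
#' reported via a message.
#'
#' @param records Redox record table (from [redox_records()]) carrying
#'   `fov_id`, `cell_id`, `condition` and `morphology` columns.
#' @param min_rois Minimum number of valid ROIs per cell (default 5).
#' @return Data frame with one row per (fov_id, cell_id, condition,
#'   morphology): `median_flirr`, `mean_flirr`, `median_e_pct`,
#'   `median_intensity_ratio`, `n_rois`.
#' @export
cell_summaries <- function(records, min_rois = 5) {
  need <- c("fov_id", "cell_id", "condition", "morphology", "flirr")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("cell_summaries: missing columns: ", paste(miss, collapse = ", "))
  rec <- records[records$flirr_valid %in% TRUE, , drop = FALSE]
  key <- interaction(rec$fov_id, rec$cell_id, rec$condition, rec$morphology,
                     drop = TRUE)
  first <- function(x) x[1]
  med_or_na <- function(x) if (all(is.na(x))) NA_real_ else stats::median(x, na.rm = TRUE)
  out <- do.call(rbind, lapply(split(rec, key), function(g) {
    data.frame(fov_id = first(g$fov_id), cell_id = first(g$cell_id),
               condition = first(g$condition), morphology = first(g$morphology),
               median_flirr = stats::median(g$flirr),
               mean_flirr = mean(g$flirr),
               median_e_pct = med_or_na(g$trp_e_pct),
               median_intensity_ratio = med_or_na(g$intensity_ratio),
               n_rois = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  drop <- out$n_rois < min_rois
  if (any(drop)) {
    message(sprintf("cell_summaries: excluding %d cell(s) with fewer than %d valid ROIs",
                    sum(drop), min_rois))
    out <- out[!drop, , drop = FALSE]
  }
  out[order(out$fov_id, out$cell_id, out$condition, out$morphology), ,
      drop = FALSE]
}

#' Percent change of the median from control to treatment
#'
#' `100 * (rx - ctrl) / ctrl`, the per-cell response measure used for
#' responder categorization.
#'
#' @param ctrl_median,rx_median Control and treatment medians (vectorized);
#'   control must be positive.
#' @return Percent change.
#' @export
#' @examples
#' percent_median_change(0.4, 0.9)  # 125
percent_median_change <- function(ctrl_median, rx_median) {
  if (any(ctrl_median <= 0, na.rm = TRUE)) {
    stop("percent_median_change: control median must be > 0")
  }
  100 * (rx_median - ctrl_median) / ctrl_median
}

#' Responder category scheme
#'
#' Ordered, non-overlapping percent-change intervals. The shipped default is
#' the three-category example scheme 25-55% (low, Category1), 55-85%
#' (medium, Category2) and 85-125% (high, Category3). Intervals are
#' half-open `[lower, upper)` with the last interval closed at its upper
#' bound, so shared endpoints resolve deterministically.
#'
#' @param labels Unique category labels.
#' @param lower,upper Interval bounds in percent, strictly increasing with
#'   `lower[i+1] >= upper[i]`.
#' @return Object of class `category_scheme` (a data frame).
#' @export
category_scheme <- function(labels = c("Category1", "Category2", "Category3"),
                            lower = c(25, 55, 85), upper = c(55, 85, 125)) {
  stopifnot(length(labels) == length(lower), length(lower) == length(upper),
            !anyDuplicated(labels), all(lower < upper))
  if (length(lower) > 1 && any(lower[-1] < upper[-length(upper)])) {
    stop("category_scheme: intervals must be non-overlapping and increasing")
  }
  structure(data.frame(label = labels, lower = lower, upper = upper,
                       stringsAsFactors = FALSE),
            class = c("category_scheme", "data.frame"))
}

#' Equal-count (tertile-style) category scheme from observed changes
#'
#' Data-driven alternative to fixed boundaries: splits the observed percent
#' changes into `n` classes with approximately equal cell counts.
#'
#' @param changes Observed percent changes.
#' @param n Number of categories.
#' @return A [category_scheme()] spanning the observed range.
#' @export
tertile_scheme <- function(changes, n = 3) {
  stopifnot(length(changes) >= n)
  q <- stats::quantile(changes, probs = seq(0, 1, length.out = n + 1), names = FALSE)
  q <- q + c(-1e-9, rep(0, n - 1), 1e-9)  # include extremes
  if (any(diff(q) <= 0)) stop("tertile_scheme: degenerate quantile boundaries")
  category_scheme(labels = paste0("Category", seq_len(n)),
                  lower = q[-(n + 1)], upper = q[-1])
}

#' Assign a percent change to a responder category
#'
#' Intervals are `[lower, upper)`, last interval `[lower, upper]`; values
#' outside every interval return `"uncategorized"` (a value, not an error).
#'
#' @param change_pct Percent change (vectorized).
#' @param scheme A [category_scheme()].
#' @return Character vector of category labels.
#' @export
#' @examples
#' categorize(c(40, 55, 10, 125), category_scheme())
categorize <- function(change_pct, scheme = category_scheme()) {
  stopifnot(inherits(scheme, "category_scheme"))
  k <- nrow(scheme)
  out <- rep("uncategorized", length(change_pct))
  for (i in seq_len(k)) {
    hit <- !is.na(change_pct) & change_pct >= scheme$lower[i] &
      (if (i == k) change_pct <= scheme$upper[i] else change_pct < scheme$upper[i])
    out[hit] <- scheme$label[i]
  }
  out[is.na(change_pct)] <- NA_character_
  out
}

#' Per-cell responder assignments from paired condition summaries
#'
#' Joins control and treatment cell summaries on (fov_id, cell_id) within the
#' chosen morphology (the categorization basis is the mitochondrial data by
#' default, matching how responder classes are defined), computes the percent
#' median FLIRR change, and assigns each cell to a category. Cells whose
#' control median is non-positive are excluded with a message.
#'
#' @param summaries Output of [cell_summaries()] covering both conditions.
#' @param control,treatment Condition labels to pair.
#' @param scheme A [category_scheme()].
#' @param basis Morphology used for categorization (`"mito"` default).
#' @return Data frame: `fov_id`, `cell_id`, `ctrl_median`, `rx_median`,
#'   `change_pct`, `category`.
#' @export
responder_assignments <- function(summaries, control, treatment,
                                  scheme = category_scheme(), basis = "mito") {
  s <- summaries[summaries$morphology == basis, , drop = FALSE]
  ctl <- s[s$condition == control, c("fov_id", "cell_id", "median_flirr")]
  trt <- s[s$condition == treatment, c("fov_id", "cell_id", "median_flirr")]
  names(ctl)[3] <- "ctrl_median"; names(trt)[3] <- "rx_median"
  m <- merge(ctl, trt, by = c("fov_id", "cell_id"))
  bad <- m$ctrl_median <= 0
  if (any(bad)) {
    message(sprintf("responder_assignments: excluding %d cell(s) with non-positive control median",
                    sum(bad)))
    m <- m[!bad, , drop = FALSE]
  }
  m$change_pct <- percent_median_change(m$ctrl_median, m$rx_median)
  m$category <- categorize(m$change_pct, scheme)
  m[order(m$fov_id, m$cell_id), , drop = FALSE]
}

#' Pool ROI-level values by responder category
#'
#' Merges ROI records across fields of view within each category, per
#' condition and morphology. Total pooled counts equal the number of ROIs
#' belonging to categorized cells; no ROI appears in two categories.
#'
#' @param assignments Output of [responder_assignments()].
#' @param records ROI redox records with `fov_id`, `cell_id`, `condition`,
#'   `morphology` columns.
#' @param value Column to pool (default `"flirr"`).
#' @return Data frame: `category`, `condition`, `morphology`, `fov_id`,
#'   `cell_id`, `value`; one row per pooled ROI.
#' @export
merge_categories <- function(assignments, records, value = "flirr") {
  key_a <- paste(assignments$fov_id, assignments$cell_id)
  key_r <- paste(records$fov_id, records$cell_id)
  idx <- match(key_r, key_a)
  keep <- !is.na(idx) & assignments$category[idx] != "uncategorized" &
    !is.na(records[[value]])
  data.frame(category = assignments$category[idx[keep]],
             condition = records$condition[keep],
             morphology = records$morphology[keep],
             fov_id = records$fov_id[keep], cell_id = records$cell_id[keep],
             value = records[[value]][keep], stringsAsFactors = FALSE)
}

#' Frequency distribution histogram
#'
#' Counts per half-open bin `[e_i, e_{i+1})`, with the last bin closed at its
#' upper edge; values outside the edges are ignored. A normalized-frequency
#' column is included.
#'
#' @param values Numeric values.
#' @param bin_edges Strictly increasing bin edges.
#' @return Data frame: `lower`, `upper`, `count`, `frequency` (count over the
#'   number of in-range values; 0 when the histogram is empty).
#' @export
frequency_distribution <- function(values, bin_edges) {
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop("frequency_distribution: bin_edges must be strictly increasing")
  }
  k <- length(bin_edges) - 1L
  values <- values[!is.na(values)]
  counts <- integer(k)
  if (length(values)) {
    ix <- findInterval(values, bin_edges, rightmost.closed = TRUE)
    ix <- ix[ix >= 1L & ix <= k]
    tab <- tabulate(ix, nbins = k)
    counts <- tab
  }
  total <- sum(counts)
  data.frame(lower = bin_edges[-(k + 1L)], upper = bin_edges[-1L],
             count = counts,
             frequency = if (total > 0) counts / total else rep(0, k))
}

#' Pearson correlation between per-cell median FLIRR and E%
#'
#' Computes the product-moment correlation on per-cell (median FLIRR, median
#' E%) pairs, pooled across the supplied conditions, separately per
#' morphology. Requires at least 3 paired cells; zero variance in either
#' variable yields `NA` with a flag.
#'
#' @param summaries Output of [cell_summaries()].
#' @param conditions Conditions to pool (default: all present).
#' @return Data frame: `morphology`, `n`, `r`, `degenerate`.
#' @export
correlate_flirr_e <- function(summaries, conditions = NULL) {
  s <- summaries
  if (!is.null(conditions)) s <- s[s$condition %in% conditions, , drop = FALSE]
  s <- s[!is.na(s$median_flirr) & !is.na(s$median_e_pct), , drop = FALSE]
  out <- do.call(rbind, lapply(split(s, s$morphology), function(g) {
    if (nrow(g) < 3) stop("correlate_flirr_e: fewer than 3 paired cells")
    degen <- stats::sd(g$median_flirr) == 0 || stats::sd(g$median_e_pct) == 0
    data.frame(morphology = g$morphology[1], n = nrow(g),
               r = if (degen) NA_real_ else
                 stats::cor(g$median_flirr, g$median_e_pct),
               degenerate = degen, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Attribute the whole-cell vs mitochondrial response difference to glycolysis
#'
#' NAD(P)H signal arises from both mitochondrial OXPHOS and cytosolic
#' glycolysis while FAD is mitochondrial only, so where the whole-cell
#' percent median change exceeds the mitochondrial one, the increment is
#' attributed to glycolysis.
#'
#' @param mito_change_pct,wholecell_change_pct Percent median changes for the
#'   same cell and condition pair (vectorized).
#' @param margin Percentage-point margin above which the cell is called
#'   glycolysis-responsive (default 5).
#' @return Data frame: `increment` (percentage points, whole-cell minus
#'   mito) and `call` (`"glycolysis-responsive"` when the increment exceeds
#'   the margin, `"OXPHOS-driven"` when its magnitude is within the margin,
#'   `"mito-dominant"` when the mitochondrial change exceeds whole-cell by
#'   more than the margin).
#' @export
#' @examples
#' glycolysis_attribution(60, 90)  # +30 points, glycolysis-responsive
glycolysis_attribution <- function(mito_change_pct, wholecell_change_pct,
                                   margin = 5) {
  increment <- wholecell_change_pct - mito_change_pct
  call <- ifelse(increment > margin, "glycolysis-responsive",
                 ifelse(abs(increment) <= margin, "OXPHOS-driven",
                        "mito-dominant"))
  data.frame(increment = increment, call = call, stringsAsFactors = FALSE)
}
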