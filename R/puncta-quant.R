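#' Per-cell puncta density and QC metrics
#'
#' Computes, for each cell, the puncta density
#' \deqn{density = 100 \times n_{puncta} / V_{nucleus}}
#' in puncta per 100 cubic micrometres, together with the mean reporter
#' intensity over the nucleus mask that the low-expression filter uses.
#' "Cell volume" is the nucleus volume, the only compartment the DAPI
#' channel defines.
#'
#' @param punctaSets list of \linkS4class{PunctaSet} from one condition /
#'   imaging session (each already carries nucleus volume and mean
#'   reporter intensity).
#' @return data frame of cell QC records: \code{cell_id}, \code{condition},
#'   \code{nucleus_volume}, \code{mean_reporter_intensity},
#'   \code{n_puncta}, \code{puncta_density},
#'   \code{excluded_small_volume}, \code{excluded_low_expression}
#'   (flags all FALSE; set by \code{\link{applyQCFilters}}).
#' @export
computeCellMetrics <- function(punctaSets) {
  stopifnot(length(punctaSets) >= 1L,
            all(vapply(punctaSets, is, logical(1), "PunctaSet")))
  rows <- lapply(punctaSets, function(ps) {
    if (ps@nucleusVolume <= 0) stop("cell ", ps@cellId, " has zero nucleus volume")
    mi <- ps@meanIntensity[["reporter"]] %||% ps@meanIntensity[[1L]]
    data.frame(
      cell_id = ps@cellId, condition = ps@condition,
      nucleus_volume = ps@nucleusVolume,
      mean_reporter_intensity = mi,
      n_puncta = nrow(ps@puncta),
      puncta_density = 100 * nrow(ps@puncta) / ps@nucleusVolume,
      excluded_small_volume = FALSE, excluded_low_expression = FALSE,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Apply the two QC exclusion rules before cross-condition comparison
#'
#' First flags cells whose nucleus volume is strictly below
#' \code{volumeCutoffUm3} (a mis-segmented or out-of-frame cell); then,
#' among the remaining cells of each condition, flags the
#' \code{floor(n * lowExpressionFraction)} cells with the lowest mean
#' reporter intensity (rank-based, ties broken by input order, i.e. by
#' cell id order within a condition). An optional expression floor first
#' removes cells that are not expressing at all from the tercile
#' computation (they are flagged low-expression directly).
#'
#' @param records data frame from \code{\link{computeCellMetrics}}.
#' @param volumeCutoffUm3 strict lower volume bound (default 200).
#' @param lowExpressionFraction fraction of expressing cells excluded from
#'   the bottom of the intensity ranking (default 1/3).
#' @param expressionFloor cells with mean reporter intensity at or below
#'   this value are treated as non-expressing (default 0 = disabled).
#' @return list with data frames \code{kept} and \code{flagged};
#'   \code{kept} and \code{flagged} partition the input rows.
#' @export
applyQCFilters <- function(records, volumeCutoffUm3 = 200,
                           lowExpressionFraction = 1 / 3,
                           expressionFloor = 0) {
  stopifnot(is.data.frame(records))
  if (!nrow(records))
    return(list(kept = records, flagged = records))
  rec <- records
  rec$excluded_small_volume <- rec$nucleus_volume < volumeCutoffUm3
  rec$excluded_low_expression <- FALSE
  for (cond in unique(rec$condition)) {
    i <- which(rec$condition == cond & !rec$excluded_small_volume)
    if (!length(i)) next
    nonexpr <- rec$mean_reporter_intensity[i] <= expressionFloor &
      expressionFloor > 0
    rec$excluded_low_expression[i[nonexpr]] <- TRUE
    expr <- i[!nonexpr]
    n_excl <- floor(length(expr) * lowExpressionFraction)
    if (n_excl >= 1L) {
      ord <- expr[order(rec$mean_reporter_intensity[expr])]  # stable
      rec$excluded_low_expression[ord[seq_len(n_excl)]] <- TRUE
    }
  }
  flagged <- rec$excluded_small_volume | rec$excluded_low_expression
  list(kept = rec[!flagged, , drop = FALSE],
       flagged = rec[flagged, , drop = FALSE])
}

#' Per-condition summary of kept cells
#'
#' @param kept data frame of kept records from \code{\link{applyQCFilters}}.
#' @return data frame with one row per condition: n cells, median density,
#'   first and third density quartiles (the numbers behind a box plot).
#' @export
summarizeConditions <- function(kept) {
  stopifnot(is.data.frame(kept))
  conds <- unique(kept$condition)
  rows <- lapply(conds, function(cond) {
    d <- kept$puncta_density[kept$condition == cond]
    data.frame(condition = cond, n_cells = length(d),
               median_density = stats::median(d),
               q1_density = unname(stats::quantile(d, 0.25)),
               q3_density = unname(stats::quantile(d, 0.75)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
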