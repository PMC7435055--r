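# Treatment-versus-control comparison: percent change of group-mean
# features, reduced to chord-plot edge lists (strongest activation and
# inhibition per drug, and per parameter).

#' Percent change of each feature under each treatment
#'
#' For every non-control treatment group, computes
#' 100 * (mean_treatment - mean_control) / mean_control per feature, with
#' group means taken over the per-organoid fitted values (missing values
#' excluded pairwise). Features whose control mean is zero are undefined and
#' reported as `NA`.
#'
#' @param cohort cohort feature table (one row per organoid) with a
#'   `treatment` column.
#' @param control_label label of the control group.
#' @param aggregate group aggregator, `"mean"` (default) or `"median"`.
#' @return Numeric matrix, treatments (rows) by features (columns), of
#'   signed percent changes.
#' @export
percent_change_table <- function(cohort, control_label = "control",
                                 aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  agg <- if (aggregate == "mean") {
    function(x) mean(x, na.rm = TRUE)
  } else {
    function(x) stats::median(x, na.rm = TRUE)
  }
  stopifnot(is.data.frame(cohort), "treatment" %in% names(cohort))
  stop_if(!control_label %in% cohort$treatment,
          sprintf("control group '%s' not present", control_label))
  params <- intersect(feature_names(), names(cohort))
  ctrl <- cohort[cohort$treatment == control_label, ]
  ctrl_mean <- vapply(params, function(p) agg(ctrl[[p]]), numeric(1))
  drugs <- setdiff(unique(cohort$treatment), control_label)
  stop_if(length(drugs) == 0, "no treatment groups besides the control")
  out <- matrix(NA_real_, nrow = length(drugs), ncol = length(params),
                dimnames = list(drugs, params))
  for (d in drugs) {
    grp <- cohort[cohort$treatment == d, ]
    m <- vapply(params, function(p) agg(grp[[p]]), numeric(1))
    pc <- 100 * (m - ctrl_mean) / ctrl_mean
    pc[ctrl_mean == 0] <- NA_real_
    out[d, ] <- pc
  }
  out
}

edge_row <- function(drug, parameter, pc) {
  data.frame(drug = drug, parameter = parameter, percent_change = pc,
             direction = if (pc > 0) "activation" else "inhibition",
             stringsAsFactors = FALSE)
}

#' Strongest activation and inhibition per drug
#'
#' For each treatment, emits at most two edges: the feature with the highest
#' positive percent change (activation) and the feature with the most
#' negative percent change (inhibition). A drug that moves every feature in
#' one direction contributes a single edge. Ties are resolved by feature
#' order (first column wins).
#'
#' @param pct matrix from [percent_change_table()].
#' @return Data frame of edges: `drug`, `parameter`, `percent_change`,
#'   `direction`.
#' @export
max_effects_per_drug <- function(pct) {
  stopifnot(is.matrix(pct), nrow(pct) >= 1)
  out <- lapply(rownames(pct), function(d) {
    v <- stats::setNames(pct[d, ], colnames(pct))
    v <- v[!is.na(v)]
    rows <- list()
    if (any(v > 0)) {
      j <- names(v)[which.max(v)]
      rows <- c(rows, list(edge_row(d, j, v[[j]])))
    }
    if (any(v < 0)) {
      j <- names(v)[which.min(v)]
      rows <- c(rows, list(edge_row(d, j, v[[j]])))
    }
    do.call(rbind, rows)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Strongest enhancing and inhibiting drug per feature
#'
#' For each feature, emits the drug with the largest positive percent change
#' and the drug with the most negative one — at most two edges, or a single
#' edge for features that every drug moves in the same direction.
#'
#' @param pct matrix from [percent_change_table()].
#' @return Data frame of edges as in [max_effects_per_drug()].
#' @export
max_effects_per_parameter <- function(pct) {
  stopifnot(is.matrix(pct), nrow(pct) >= 1)
  out <- lapply(colnames(pct), function(p) {
    v <- stats::setNames(pct[, p], rownames(pct))
    v <- v[!is.na(v)]
    rows <- list()
    if (any(v > 0)) {
      d <- names(v)[which.max(v)]
      rows <- c(rows, list(edge_row(d, p, v[[d]])))
    }
    if (any(v < 0)) {
      d <- names(v)[which.min(v)]
      rows <- c(rows, list(edge_row(d, p, v[[d]])))
    }
    do.call(rbind, rows)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write a chord edge list to CSV
#'
#' Columns `source`, `target`, `percent_change`, `direction`; an empty edge
#' list produces a header-only file. The edge list is the hand-off format
#' for circular chord-diagram rendering.
#'
#' @param edges data frame from [max_effects_per_drug()] or
#'   [max_effects_per_parameter()] (may be `NULL`/empty).
#' @param path output file path.
#' @return The path, invisibly.
#' @export
export_chord_edges <- function(edges, path) {
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(source = character(0), target = character(0),
                        percent_change = numeric(0),
                        direction = character(0))
  } else {
    names(edges)[names(edges) == "drug"] <- "source"
    names(edges)[names(edges) == "parameter"] <- "target"
  }
  utils::write.csv(edges, path, row.names = FALSE)
  invisible(path)
}

#' Read a chord edge list written by [export_chord_edges()]
#'
#' @param path CSV path.
#' @return Data frame with columns `source`, `target`, `percent_change`,
#'   `direction`.
#' @export
read_chord_edges <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
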